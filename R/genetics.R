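#' Variance components from the augmented ANOVA
#'
#' Error variance is the residual mean square; genotypic variance is the
#' accession mean square minus the error mean square (floored at zero when
#' the accession MS falls below the residual MS); phenotypic variance is
#' their sum, i.e. the accession mean square itself unless flooring
#' occurred.
#'
#' @param anova An [augmented_anova()] object, or a list of them.
#' @return A tibble with columns `trait`, `var_e`, `var_g`, `var_p`,
#'   `floored` (logical: negative genotypic estimate floored at 0).
#' @examples
#' variance_components_ms(ms_genotype = 1507.87, ms_error = 84.28)
#' @export
variance_components <- function(anova) {
  if (inherits(anova, "augmented_anova")) anova <- list(anova)
  purrr::map_dfr(anova, function(a) {
    ms_g <- a$table$meansq[a$table$term == "Accession"]
    ms_e <- a$table$meansq[a$table$term == "Residual"]
    dplyr::mutate(variance_components_ms(ms_g, ms_e), trait = a$trait,
                  .before = 1)
  })
}

#' @rdname variance_components
#' @param ms_genotype Accession (genotype) mean square.
#' @param ms_error Residual (error) mean square.
#' @export
variance_components_ms <- function(ms_genotype, ms_error) {
  var_g_raw <- ms_genotype - ms_error
  floored <- var_g_raw < 0
  var_g <- pmax(0, var_g_raw)
  if (any(floored)) {
    warn("negative genotypic variance estimate floored at 0")
  }
  tibble(var_e = ms_error, var_g = var_g, var_p = var_g + ms_error,
         floored = floored)
}

#' Coefficient of variation from a variance and a mean
#'
#' \eqn{CV = 100 \sqrt{\sigma^2} / \bar{X}}.  Applied to the genotypic
#' variance this is the GCV, to the phenotypic variance the PCV.
#'
#' @param variance Variance in squared trait units (`>= 0`).
#' @param mean Trait mean (`> 0`).
#' @return Percentage.
#' @examples
#' coefficient_of_variation(1423.59, 221.00)  # 17.07
#' @export
coefficient_of_variation <- function(variance, mean) {
  if (any(mean <= 0)) abort("domain error: mean must be > 0")
  if (any(variance < 0)) abort("domain error: variance must be >= 0")
  100 * sqrt(variance) / mean
}

#' Broad-sense heritability
#'
#' \eqn{h^2 = 100\,\sigma^2_g / \sigma^2_p}, the share of phenotypic
#' variance that is genotypic.
#'
#' @param var_g Genotypic variance.
#' @param var_p Phenotypic variance (`> 0`; `0` returns `NA` with a
#'   degenerate warning).
#' @return Percentage in `[0, 100]`.
#' @examples
#' heritability(1423.59, 1507.87)  # 94.41
#' @export
heritability <- function(var_g, var_p) {
  out <- ifelse(var_p > 0, 100 * var_g / var_p, NA_real_)
  if (any(var_p <= 0)) warn("degenerate: phenotypic variance is zero")
  out
}

#' Expected genetic advance under truncation selection
#'
#' \eqn{GA = k\, h^2\, \sigma_p} with \eqn{h^2} as a fraction and k the
#' standardised selection differential (2.063 at a 5% selected fraction);
#' GAM expresses GA as a percentage of the trait mean.
#'
#' @param h2 Broad-sense heritability as a fraction in `[0, 1]`.
#' @param sd_p Phenotypic standard deviation (trait units, `>= 0`).
#' @param mean Trait mean (`> 0`).
#' @param k Selection-intensity constant (`> 0`).
#' @return A tibble with columns `ga` (trait units) and `gam` (%).
#' @examples
#' genetic_advance(0.9441066, sqrt(1507.87), 221.00)  # GA 75.63, GAM 34.22
#' @export
genetic_advance <- function(h2, sd_p, mean, k = 2.063) {
  if (any(mean <= 0)) abort("domain error: mean must be > 0")
  if (any(sd_p < 0)) abort("domain error: sd_p must be >= 0")
  if (any(k <= 0)) abort("domain error: k must be > 0")
  ga <- k * h2 * sd_p
  tibble(ga = ga, gam = 100 * ga / mean)
}

#' Low / medium / high bands for coefficients of variation and GAM
#'
#' Standard bands: low below 10%, medium 10-20%, high above 20%.
#'
#' @param value Percentage (`>= 0`).
#' @return `"L"`, `"M"` or `"H"`.
#' @examples
#' categorize_cv(c(5.57, 17.07, 26.62))  # L M H
#' @export
categorize_cv <- function(value) {
  dplyr::case_when(is.na(value) ~ NA_character_,
                   value < 10 ~ "L",
                   value <= 20 ~ "M",
                   TRUE ~ "H")
}

#' Heritability bands
#'
#' Low 0-30%, moderate 30-60%, high above 60%.
#'
#' @param value Heritability percentage.
#' @return `"L"`, `"M"` or `"H"`.
#' @export
categorize_h2 <- function(value) {
  dplyr::case_when(is.na(value) ~ NA_character_,
                   value <= 30 ~ "L",
                   value <= 60 ~ "M",
                   TRUE ~ "H")
}

#' Genetic variability parameters from printed mean squares
#'
#' The core estimator chain on already-summarised inputs: accession and
#' residual mean squares plus the trait mean give the variance components,
#' GCV/PCV, broad-sense heritability, genetic advance and GAM, with their
#' L/M/H categories.
#'
#' @param ms_genotype,ms_error Accession and residual mean squares.
#' @param mean Trait mean (of adjusted genotype means).
#' @param trait Optional trait label(s).
#' @param k Selection-intensity constant.
#' @return One row per trait: `trait`, `var_p`, `var_g`, `var_e`, `mean`,
#'   `gcv`, `gcv_cat`, `pcv`, `pcv_cat`, `h2`, `h2_cat`, `ga`, `gam`,
#'   `gam_cat`, `floored`.
#' @examples
#' variability_from_ms(1507.87, 84.28, 221.00, trait = "PH")
#' @export
variability_from_ms <- function(ms_genotype, ms_error, mean,
                                trait = NULL, k = 2.063) {
  vc <- variance_components_ms(ms_genotype, ms_error)
  gcv <- coefficient_of_variation(vc$var_g, mean)
  pcv <- coefficient_of_variation(vc$var_p, mean)
  h2 <- heritability(vc$var_g, vc$var_p)
  adv <- genetic_advance(h2 / 100, sqrt(vc$var_p), mean, k)
  tibble(
    trait = trait %||% paste0("trait", seq_along(gcv)),
    var_p = vc$var_p, var_g = vc$var_g, var_e = vc$var_e, mean = mean,
    gcv = gcv, gcv_cat = categorize_cv(gcv),
    pcv = pcv, pcv_cat = categorize_cv(pcv),
    h2 = h2, h2_cat = categorize_h2(h2),
    ga = adv$ga, gam = adv$gam, gam_cat = categorize_cv(adv$gam),
    floored = vc$floored
  )
}

#' Genetic variability parameters for a trial
#'
#' Runs the augmented ANOVA per trait and derives the full variability
#' table; trait means are the means of the adjusted genotype means.
#'
#' @param trial An [augmented_trial()].
#' @param traits Trait abbreviations; default all.
#' @param k Selection-intensity constant (2.063 at a 5% selected fraction).
#' @return A tibble as in [variability_from_ms()].
#' @examples
#' sim <- simulate_trial(landrace_sim_config(n_tests = 30), seed = 1)
#' genetic_variability(sim$trial, traits = c("PH", "FW"))
#' @export
genetic_variability <- function(trial, traits = NULL, k = 2.063) {
  stopifnot(inherits(trial, "augmented_trial"))
  traits <- traits %||% trial$traits$abbr
  means <- adjusted_means(trial, traits)
  purrr::map_dfr(traits, function(tr) {
    a <- augmented_anova(trial, tr)
    variability_from_ms(
      ms_genotype = a$table$meansq[a$table$term == "Accession"],
      ms_error = a$table$meansq[a$table$term == "Residual"],
      mean = base::mean(means[[tr]], na.rm = TRUE),
      trait = tr, k = k)
  })
}

#' Descriptive statistics of adjusted genotype means
#'
#' @param means A data frame of per-genotype values (e.g. from
#'   [adjusted_means()]) with one numeric column per trait.
#' @param traits Trait columns; default every numeric column.
#' @return A tibble: `trait`, `max`, `min`, `mean`, `sd` (sample, n-1
#'   denominator), `cv` (%).  Fewer than two genotypes flags the trait
#'   degenerate (`NA` sd/cv).
#' @examples
#' descriptive_stats(data.frame(PH = c(1, 2, 3)))
#' @export
descriptive_stats <- function(means, traits = NULL) {
  means <- as_tibble(means)
  traits <- traits %||%
    names(means)[vapply(means, is.numeric, logical(1))]
  purrr::map_dfr(traits, function(tr) {
    x <- means[[tr]]
    x <- x[!is.na(x)]
    if (length(x) < 2) {
      return(tibble(trait = tr, max = if (length(x)) max(x) else NA_real_,
                    min = if (length(x)) min(x) else NA_real_,
                    mean = if (length(x)) mean(x) else NA_real_,
                    sd = NA_real_, cv = NA_real_))
    }
    m <- mean(x); s <- sd(x)
    tibble(trait = tr, max = max(x), min = min(x), mean = m, sd = s,
           cv = if (m != 0) 100 * s / m else NA_real_)
  })
}
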