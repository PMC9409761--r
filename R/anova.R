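#' Estimate block effects from the replicated checks
#'
#' In an augmented RCBD only the checks are replicated across blocks, so
#' the block effect is estimated from them alone: effect of block j =
#' (mean of check plots in block j) - (grand mean of all check plots).
#' Effects sum to zero by construction.
#'
#' @param trial An [augmented_trial()].
#' @param trait Trait abbreviation.
#' @return A tibble with columns `block`, `effect`; the grand check mean is
#'   attached as attribute `grand_check_mean`.
#' @examples
#' sim <- simulate_trial(landrace_sim_config(), seed = 1)
#' block_effects(sim$trial, "PH")
#' @export
block_effects <- function(trial, trait) {
  stopifnot(inherits(trial, "augmented_trial"))
  if (!trait %in% trial$traits$abbr) {
    abort(paste0("unknown trait: ", trait))
  }
  chk <- trial$plots[trial$plots$role == "check",
                     c("block", "genotype", trait)]
  y <- chk[[trait]]
  if (anyNA(y)) {
    i <- which(is.na(y))[1]
    abort(paste0("adjustment error: check ", chk$genotype[i],
                 " has no value for trait ", trait, " in block ",
                 chk$block[i]),
          class = "phenodiv_adjustment_error")
  }
  grand <- mean(y)
  eff <- tapply(y, chk$block, mean) - grand
  out <- tibble(block = names(eff), effect = as.numeric(eff))
  out <- arrange(out, .data$block)
  attr(out, "grand_check_mean") <- grand
  out
}

#' Block-adjusted genotype means
#'
#' Test entries are observed once; their adjusted value is the observation
#' minus the estimated effect of the block they sat in.  Checks are
#' averaged over their b plots (block effects cancel by construction of the
#' design).
#'
#' @param trial An [augmented_trial()].
#' @param traits Trait abbreviations (default: all traits in the trial).
#' @return A wide tibble: `genotype`, `role`, one column of adjusted means
#'   per trait.  Rows ordered checks then tests, each alphabetically.
#' @examples
#' sim <- simulate_trial(landrace_sim_config(n_tests = 20), seed = 1)
#' adjusted_means(sim$trial, c("PH", "FW"))
#' @export
adjusted_means <- function(trial, traits = NULL) {
  stopifnot(inherits(trial, "augmented_trial"))
  traits <- traits %||% trial$traits$abbr
  ids <- c(trial$checks, trial$tests)
  out <- tibble(genotype = ids,
                role = c(rep("check", length(trial$checks)),
                         rep("test", length(trial$tests))))
  for (tr in traits) {
    eff <- block_effects(trial, tr)
    effmap <- setNames(eff$effect, eff$block)
    p <- trial$plots
    adj <- rep(NA_real_, length(ids))
    chk <- p[p$role == "check", ]
    cm <- tapply(chk[[tr]], chk$genotype, mean)
    adj[match(names(cm), ids)] <- as.numeric(cm)
    tst <- p[p$role == "test" & !is.na(p[[tr]]), ]
    adj[match(tst$genotype, ids)] <- tst[[tr]] - effmap[tst$block]
    out[[tr]] <- adj
  }
  out
}

#' Treatment-adjusted ANOVA for one trait of an augmented RCBD
#'
#' Decomposes variation into Block, Treatment (all genotypes, adjusted
#' for blocks), its partition into Check, Accession (test entries) and
#' the single-degree-of-freedom Accession-vs-Check contrast, and the
#' Residual estimated from the check-by-block interaction.  The treatment
#' partition is computed by exact sequential least squares on the
#' genotype + block model (blocks first, then the check/test group
#' contrast, then check identities, then test identities), so the
#' Accession F-test keeps its nominal size; the residual mean square is
#' identical to the residual of an ordinary least-squares fit of genotype
#' + block to all plots.  All F tests are against the residual mean
#' square; significance codes are `**` (p <= 0.01), `*` (p <= 0.05),
#' `ns` otherwise.
#'
#' The Block row is the checks-based block sum of squares (the b-1 block
#' contrasts estimated from the replicated checks), reported for
#' completeness; block and treatment are not orthogonal in this design.
#'
#' With b blocks, c checks and n test entries the degrees of freedom are
#' Block b-1, Treatment c+n-1 = Check (c-1) + Accession (n-1) +
#' Accession-vs-Check (1), Residual (b-1)(c-1).
#'
#' @param trial An [augmented_trial()].
#' @param trait Trait abbreviation.
#' @return An object of class `augmented_anova`: list with `table` (tibble:
#'   `term`, `df`, `sumsq`, `meansq`, `statistic`, `p.value`, `signif`),
#'   `trait`, `r` (check replication = number of blocks), `degenerate`.
#' @examples
#' sim <- simulate_trial(landrace_sim_config(n_tests = 20), seed = 1)
#' augmented_anova(sim$trial, "PH")
#' @export
augmented_anova <- function(trial, trait) {
  stopifnot(inherits(trial, "augmented_trial"))
  b <- length(trial$blocks)
  cc <- length(trial$checks)
  if ((b - 1) * (cc - 1) < 1) {
    abort("design too small: residual needs (b-1)(c-1) >= 1",
          class = "phenodiv_design_error")
  }
  p <- trial$plots
  chk <- p[p$role == "check", c("block", "genotype", trait)]
  y <- chk[[trait]]
  if (anyNA(y)) {
    abort(paste0("adjustment error: missing check value for ", trait),
          class = "phenodiv_adjustment_error")
  }
  grand_chk <- mean(y)
  cmean <- tapply(y, chk$genotype, mean)          # per check
  bmean <- tapply(y, chk$block, mean)             # per block

  # residual: check x block interaction; identical to the RSS of the
  # full genotype + block least-squares fit (tests are saturated)
  fitted <- cmean[chk$genotype] + bmean[chk$block] - grand_chk
  ss_res <- sum((y - fitted)^2)
  df_res <- (b - 1) * (cc - 1)

  ss_block <- cc * sum((bmean - grand_chk)^2)
  ss_check <- b * sum((cmean - grand_chk)^2)

  tst <- p[p$role == "test" & !is.na(p[[trait]]), c("block", trait)]
  n <- nrow(tst)
  if (n < 2) abort("design too small: need at least 2 test entries with data",
                   class = "phenodiv_design_error")

  # sequential least-squares partition, blocks fitted first
  yy <- c(y, tst[[trait]])
  blk <- factor(c(chk$block, tst$block))
  rss_block <- sum(tapply(yy, blk, function(v) sum((v - mean(v))^2)))
  ss_trt <- rss_block - ss_res

  # + check/test group contrast (adjusted for blocks)
  x <- cbind(1, stats::model.matrix(~ blk)[, -1, drop = FALSE],
             group = rep(c(0, 1), c(length(y), n)))
  rss_bg <- sum(stats::lm.fit(x, yy)$residuals^2)
  ss_avc <- rss_block - rss_bg

  # test identities absorb the remainder of the treatment space
  ss_acc <- ss_trt - ss_check - ss_avc

  terms <- tibble(
    term = c("Block", "Treatment", "Check", "Accession",
             "Accession vs Check", "Residual"),
    df = c(b - 1, cc + n - 1, cc - 1, n - 1, 1, df_res),
    sumsq = c(ss_block, ss_trt, ss_check, ss_acc, ss_avc, ss_res)
  )
  terms$meansq <- terms$sumsq / terms$df
  ms_res <- terms$meansq[terms$term == "Residual"]

  degenerate <- ms_res <= 0 || !is.finite(ms_res) ||
    all(terms$sumsq < .Machine$double.eps * 100)
  if (degenerate || ms_res == 0) {
    terms$statistic <- NA_real_
    terms$p.value <- NA_real_
  } else {
    terms$statistic <- ifelse(terms$term == "Residual", NA_real_,
                              terms$meansq / ms_res)
    terms$p.value <- ifelse(is.na(terms$statistic), NA_real_,
                            pf(terms$statistic, terms$df, df_res,
                               lower.tail = FALSE))
  }
  terms$signif <- significance_code(terms$p.value)

  structure(list(table = terms, trait = trait, r = b,
                 degenerate = degenerate,
                 n_checks = cc, n_tests = n, n_blocks = b),
            class = "augmented_anova")
}

#' Significance codes at the 5% and 1% levels
#'
#' @param p Numeric vector of p-values.
#' @return `"**"` for p <= 0.01, `"*"` for p <= 0.05, `"ns"` otherwise;
#'   `NA` stays `NA`.
#' @export
significance_code <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p <= 0.01 ~ "**",
    p <= 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' @export
print.augmented_anova <- function(x, ...) {
  cat("Augmented RCBD ANOVA -- trait ", x$trait,
      if (x$degenerate) "  [degenerate: no residual variation]", "\n",
      sep = "")
  print(as.data.frame(x$table), row.names = FALSE, digits = 5)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.augmented_anova <- function(x, ...) {
  dplyr::mutate(x$table, trait = x$trait, .before = 1)
}

#' @exportS3Method generics::glance
glance.augmented_anova <- function(x, ...) {
  acc <- x$table[x$table$term == "Accession", ]
  tibble(trait = x$trait, n_blocks = x$n_blocks, n_checks = x$n_checks,
         n_tests = x$n_tests,
         ms_accession = acc$meansq,
         ms_residual = x$table$meansq[x$table$term == "Residual"],
         statistic = acc$statistic, p.value = acc$p.value,
         degenerate = x$degenerate)
}

#' ANOVA across all (or selected) traits, stacked tidy
#'
#' @param trial An [augmented_trial()].
#' @param traits Trait abbreviations; default all.
#' @return A tibble: one row per trait x source, columns as in
#'   [tidy.augmented_anova()].
#' @export
anova_table_all <- function(trial, traits = NULL) {
  traits <- traits %||% trial$traits$abbr
  purrr::map_dfr(traits, function(tr) tidy(augmented_anova(trial, tr)))
}
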