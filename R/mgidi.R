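#' Goal-directed 0-100 rescaling of trait means
#'
#' Each trait is linearly rescaled so that 100 is the most desirable value
#' observed: for `goal = "increase"` the trait maximum maps to 100 and the
#' minimum to 0; for `goal = "decrease"` the direction is flipped.  The
#' ideotype is the (virtual) genotype scoring 100 on every trait.
#' Constant traits cannot be rescaled and are dropped with a warning.
#'
#' @param means Per-genotype adjusted means (tibble with `genotype` plus
#'   numeric trait columns).
#' @param goals Named character vector or trait dictionary mapping trait
#'   to `"increase"`/`"decrease"`; unnamed traits default to
#'   `"increase"`.
#' @param traits Trait columns; default all numeric.
#' @return A `rescaled_matrix` object: genotype x trait matrix in
#'   `[0, 100]` with attributes `goals`, `ranges` (original min/max).
#' @examples
#' m <- data.frame(genotype = c("a", "b", "c"), PH = c(1, 2, 3))
#' rescale_traits(m)
#' @export
rescale_traits <- function(means, goals = NULL, traits = NULL) {
  m <- means_matrix(means, traits)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (is.data.frame(goals)) goals <- setNames(goals$goal, goals$abbr)
  gl <- setNames(rep("increase", ncol(m)), colnames(m))
  if (!is.null(goals)) {
    known <- intersect(names(goals), colnames(m))
    gl[known] <- goals[known]
  }
  bad <- setdiff(unique(gl), c("increase", "decrease"))
  if (length(bad)) abort("goals must be 'increase' or 'decrease'")
  rng <- apply(m, 2, range)
  constant <- colnames(m)[rng[1, ] == rng[2, ]]
  if (length(constant)) {
    warn(paste0("constant trait(s) excluded from rescaling: ",
                paste(constant, collapse = ", ")))
    keep <- setdiff(colnames(m), constant)
    m <- m[, keep, drop = FALSE]
    rng <- rng[, keep, drop = FALSE]
    gl <- gl[keep]
  }
  if (!ncol(m)) abort("no rescalable traits")
  span <- rng[2, ] - rng[1, ]
  r <- sweep(sweep(m, 2, rng[1, ], "-"), 2, span, "/") * 100
  flip <- gl == "decrease"
  r[, flip] <- 100 - r[, flip, drop = FALSE]
  structure(r, goals = gl, ranges = rng, class = c("rescaled_matrix",
                                                   class(r)))
}

#' Varimax-rotated factor model of a rescaled trait matrix
#'
#' Eigendecomposes the correlation matrix of the rescaled traits, retains
#' factors with eigenvalue >= 1 (Kaiser rule), forms initial loadings as
#' eigenvectors scaled by the square roots of their eigenvalues, applies
#' varimax rotation (no row normalisation; tolerance 1e-6), and computes
#' factor scores by ordinary-least-squares projection
#' \eqn{F = Z A (A'A)^{-1}}, where Z is the column-standardised rescaled
#' matrix.  The ideotype (100 on every trait) is standardised with the
#' genotypes' means and SDs and projected the same way.
#'
#' @param rescaled A [rescale_traits()] matrix.
#' @return Object of class `factor_model`: `loadings` (rotated, trait x
#'   factor), `initial_loadings`, `eigenvalues`, `n_factors`,
#'   `communality`, `uniqueness`, `scores` (genotype x factor),
#'   `ideotype_scores`, `rotation` matrix.
#' @export
factor_model <- function(rescaled) {
  x <- unclass(rescaled)
  if (ncol(x) < 2) abort("need at least 2 traits")
  if (nrow(x) < 3) abort("need at least 3 genotypes")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  z <- scale(x, center = ctr, scale = scl)
  cr <- stats::cor(z)
  e <- eigen(cr, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  f <- sum(lam >= 1)
  if (f == 0) {
    abort("domain error: no factor with eigenvalue >= 1; reduce traits")
  }
  v <- e$vectors[, seq_len(f), drop = FALSE]
  for (j in seq_len(f)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  init <- sweep(v, 2, sqrt(lam[seq_len(f)]), "*")
  dimnames(init) <- list(colnames(x), paste0("FA", seq_len(f)))
  if (f > 1) {
    rot <- varimax(init, normalize = FALSE, eps = 1e-6)
    a <- unclass(rot$loadings)
    rotmat <- rot$rotmat
  } else {
    a <- init
    rotmat <- matrix(1, 1, 1)
  }
  dimnames(a) <- dimnames(init)
  communality <- rowSums(a^2)
  scores <- z %*% a %*% solve(crossprod(a))
  ideo <- (rep(100, ncol(x)) - ctr) / scl
  ideo_scores <- drop(ideo %*% a %*% solve(crossprod(a)))
  structure(list(loadings = a, initial_loadings = init,
                 eigenvalues = lam, n_factors = f,
                 communality = communality,
                 uniqueness = 1 - communality,
                 scores = scores, ideotype_scores = ideo_scores,
                 rotation = rotmat, center = ctr, scale = scl),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Factor model: ", x$n_factors, " factor(s) retained of ",
      length(x$eigenvalues), " traits (",
      round(100 * sum(x$eigenvalues[seq_len(x$n_factors)]) /
              sum(x$eigenvalues), 2), "% of variance)\n", sep = "")
  invisible(x)
}

#' Multi-trait genotype-ideotype distance index
#'
#' MGIDI ranks genotypes by their Euclidean distance, in rotated factor
#' space, from an ideotype that scores 100 on every (goal-directed
#' rescaled) trait:
#' \deqn{MGIDI_i = \sqrt{\sum_{j=1}^{f} (\gamma_{ij} - \gamma_j)^2}}
#' where \eqn{\gamma_{ij}} is genotype i's score on factor j and
#' \eqn{\gamma_j} the ideotype's.  Lower is better.  Factor contributions
#' \eqn{\omega_{ij} = (\gamma_{ij}-\gamma_j)^2 / MGIDI_i^2} sum to one per
#' genotype and show which factor keeps a genotype from the ideotype.
#'
#' @param means Per-genotype adjusted means (tibble with `genotype` column
#'   plus numeric trait columns, e.g. [adjusted_means()]).
#' @param goals Trait goals, as in [rescale_traits()]; a trait dictionary
#'   also works.
#' @param intensity Selected fraction in (0, 1]; the selected count is
#'   `round(intensity * n)` (half up), the lowest-index genotypes.
#' @param traits Trait columns; default all numeric.
#' @return Object of class `mgidi_result`: `index` tibble (`genotype`,
#'   `mgidi`, `rank`, `selected`), `contributions` (genotype x factor
#'   proportions), `factor_model`, `selected` ids, `differentials`
#'   (per-trait selection differential: `trait`, `mean_all`,
#'   `mean_selected`, `sd`, `sd_pct`, `goal`), `intensity`.
#' @examples
#' sim <- simulate_trial(landrace_sim_config(n_tests = 30), seed = 1)
#' res <- mgidi(adjusted_means(sim$trial), goals = cucumber_traits())
#' head(tidy(res))
#' @export
mgidi <- function(means, goals = NULL, intensity = 0.20, traits = NULL) {
  if (intensity <= 0 || intensity > 1) {
    abort("selection intensity must be in (0, 1]")
  }
  resc <- rescale_traits(means, goals = goals, traits = traits)
  fm <- factor_model(resc)
  dev <- sweep(fm$scores, 2, fm$ideotype_scores, "-")
  d2 <- rowSums(dev^2)
  index <- sqrt(d2)
  contrib <- dev^2 / ifelse(d2 > 0, d2, 1)
  contrib[d2 == 0, ] <- 1 / fm$n_factors   # on the ideotype: split evenly
  gid <- rownames(fm$scores)
  ord <- order(index, gid)                 # ties broken by genotype id
  rank <- integer(length(index))
  rank[ord] <- seq_along(ord)
  n_sel <- floor(intensity * length(index) + 0.5)   # round half up
  n_sel <- max(1L, min(length(index), n_sel))
  selected_ids <- gid[ord][seq_len(n_sel)]

  idx <- tibble(genotype = gid, mgidi = unname(index), rank = rank,
                selected = gid %in% selected_ids) %>%
    arrange(.data$rank)

  x <- unclass(resc)
  orig <- means_matrix(means, colnames(x))
  orig <- orig[rownames(x), , drop = FALSE]
  mean_all <- colMeans(orig)
  mean_sel <- colMeans(orig[selected_ids, , drop = FALSE])
  goals_v <- attr(resc, "goals")
  differentials <- tibble(
    trait = colnames(orig),
    goal = unname(goals_v[colnames(orig)]),
    mean_all = unname(mean_all), mean_selected = unname(mean_sel),
    sd = unname(mean_sel - mean_all),
    sd_pct = unname(ifelse(mean_all != 0,
                           100 * (mean_sel - mean_all) / mean_all,
                           NA_real_))
  )

  structure(list(index = idx, contributions = contrib,
                 factor_model = fm, selected = selected_ids,
                 differentials = differentials, intensity = intensity),
            class = "mgidi_result")
}

#' @export
print.mgidi_result <- function(x, ...) {
  cat("MGIDI over ", nrow(x$index), " genotypes, ",
      x$factor_model$n_factors, " factor(s); ",
      length(x$selected), " selected at intensity ", x$intensity, "\n",
      sep = "")
  print(as.data.frame(head(x$index, 5)), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mgidi_result <- function(x, ...) x$index

#' @exportS3Method generics::glance
glance.mgidi_result <- function(x, ...) {
  lam <- x$factor_model$eigenvalues
  f <- x$factor_model$n_factors
  tibble(n_genotypes = nrow(x$index), n_factors = f,
         variance_retained = 100 * sum(lam[seq_len(f)]) / sum(lam),
         n_selected = length(x$selected), intensity = x$intensity)
}

#' Selection differentials of an MGIDI result
#'
#' @param x An [mgidi()] result.
#' @param h2 Optional named vector of broad-sense heritabilities (%) per
#'   trait; when given, the expected selection gain
#'   `gain_pct = sd_pct * h2 / 100` is appended.
#' @return The `differentials` tibble, optionally with `gain_pct`.
#' @export
selection_differentials <- function(x, h2 = NULL) {
  stopifnot(inherits(x, "mgidi_result"))
  d <- x$differentials
  if (!is.null(h2)) {
    d$gain_pct <- d$sd_pct * unname(h2[d$trait]) / 100
  }
  d
}
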