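# extract the genotype x trait numeric matrix from a means tibble
means_matrix <- function(means, traits = NULL) {
  means <- as_tibble(means)
  if (!"genotype" %in% names(means)) {
    abort("means table needs a genotype column")
  }
  traits <- traits %||%
    setdiff(names(means)[vapply(means, is.numeric, logical(1))], "genotype")
  m <- as.matrix(means[, traits, drop = FALSE])
  rownames(m) <- means$genotype
  m[, traits, drop = FALSE]
}

#' Pairwise Pearson correlations with significance
#'
#' Correlations between traits across genotypes (complete cases per pair);
#' two-sided p-values from the t reference with n-2 degrees of freedom,
#' starred `***` (p <= 0.001), `**` (p <= 0.01), `*` (p <= 0.05).
#'
#' @param means Per-genotype adjusted means (tibble with `genotype` plus
#'   numeric trait columns, e.g. from [adjusted_means()]).
#' @param traits Trait columns; default all numeric.
#' @return Object of class `trait_correlations`: list with matrices `r`,
#'   `p.value`, `n` and character matrix `stars`; constant traits are
#'   reported in `$constant` and their pairs left `NA`.
#' @examples
#' sim <- simulate_trial(landrace_sim_config(n_tests = 30), seed = 1)
#' trait_correlations(adjusted_means(sim$trial), c("PH", "FW", "YP"))
#' @export
trait_correlations <- function(means, traits = NULL) {
  m <- means_matrix(means, traits)
  if (nrow(m) < 3) abort("need at least 3 genotypes")
  sds <- apply(m, 2, sd, na.rm = TRUE)
  constant <- colnames(m)[!is.na(sds) & sds == 0]
  if (length(constant)) {
    warn(paste0("constant trait(s), correlations undefined: ",
                paste(constant, collapse = ", ")))
  }
  p <- ncol(m)
  r <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  pv <- r
  nn <- matrix(NA_integer_, p, p, dimnames = dimnames(r))
  for (i in seq_len(p)) {
    for (j in seq_len(i)) {
      ok <- stats::complete.cases(m[, i], m[, j])
      n <- sum(ok)
      nn[i, j] <- nn[j, i] <- n
      if (colnames(m)[i] %in% constant || colnames(m)[j] %in% constant) next
      if (i == j) {
        r[i, j] <- 1
        pv[i, j] <- 0
        next
      }
      rij <- cor(m[ok, i], m[ok, j])
      r[i, j] <- r[j, i] <- rij
      tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      pij <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
      pv[i, j] <- pv[j, i] <- pij
    }
  }
  pvv <- as.vector(pv)
  stars <- matrix(dplyr::case_when(is.na(pvv) ~ "",
                                   pvv <= 0.001 ~ "***",
                                   pvv <= 0.01 ~ "**",
                                   pvv <= 0.05 ~ "*",
                                   .default = ""),
                  p, p, dimnames = dimnames(r))
  structure(list(r = r, p.value = pv, n = nn, stars = stars,
                 constant = constant),
            class = "trait_correlations")
}

#' @export
print.trait_correlations <- function(x, ...) {
  cat("Trait correlations (", ncol(x$r), " traits)\n", sep = "")
  print(round(x$r, 2))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trait_correlations <- function(x, ...) {
  cn <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(trait1 = cn[idx[, 1]], trait2 = cn[idx[, 2]],
         estimate = x$r[idx], p.value = x$p.value[idx],
         n = x$n[idx], stars = x$stars[idx])
}

#' Principal component analysis of standardised trait means
#'
#' Traits are standardised to zero mean and unit variance (n-1
#' denominator) and the correlation matrix eigendecomposed.  Eigenvalues
#' therefore sum to the number of traits; components with eigenvalue >= 1
#' are retained (Kaiser rule).  Sign convention: each eigenvector's
#' largest-magnitude loading is positive.
#'
#' @param means Per-genotype adjusted means.
#' @param traits Trait columns; default all numeric.
#' @return Object of class `trait_pca`: `eigenvalues` tibble (`component`,
#'   `eigenvalue`, `proportion`, `cumulative`), `loadings` (trait x
#'   component unit eigenvectors), `scores` (genotype x component),
#'   `n_retained`, `center`, `scale`, `rank_deficient` flag.
#' @examples
#' sim <- simulate_trial(landrace_sim_config(n_tests = 30), seed = 1)
#' trait_pca(adjusted_means(sim$trial))
#' @export
trait_pca <- function(means, traits = NULL) {
  m <- means_matrix(means, traits)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (ncol(m) < 2) abort("need at least 2 traits")
  if (nrow(m) < 3) abort("need at least 3 genotypes")
  ctr <- colMeans(m)
  scl <- apply(m, 2, sd)
  if (any(scl == 0)) {
    abort(paste0("constant trait(s): ",
                 paste(colnames(m)[scl == 0], collapse = ", ")))
  }
  z <- scale(m, center = ctr, scale = scl)
  cr <- stats::cor(z)
  e <- eigen(cr, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  v <- e$vectors
  # sign convention: largest |loading| positive
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  dimnames(v) <- list(colnames(m), paste0("PC", seq_len(ncol(v))))
  scores <- z %*% v
  p <- ncol(m)
  rank_deficient <- sum(lam > 1e-10 * lam[1]) < p
  eig <- tibble(component = paste0("PC", seq_len(p)),
                eigenvalue = lam,
                proportion = 100 * lam / sum(lam),
                cumulative = cumsum(100 * lam / sum(lam)))
  structure(list(eigenvalues = eig, loadings = v, scores = scores,
                 n_retained = sum(lam >= 1), center = ctr, scale = scl,
                 rank_deficient = rank_deficient),
            class = "trait_pca")
}

#' @export
print.trait_pca <- function(x, ...) {
  cat("PCA of ", nrow(x$loadings), " traits, ", nrow(x$scores),
      " genotypes; ", x$n_retained,
      " component(s) retained (eigenvalue >= 1)\n", sep = "")
  print(as.data.frame(head(x$eigenvalues, x$n_retained)),
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trait_pca <- function(x, matrix = c("eigenvalues", "loadings",
                                         "scores"), ...) {
  matrix <- match.arg(matrix)
  switch(matrix,
    eigenvalues = x$eigenvalues,
    loadings = as_tibble(x$loadings, rownames = "trait"),
    scores = as_tibble(x$scores, rownames = "genotype"))
}

#' @exportS3Method generics::glance
glance.trait_pca <- function(x, ...) {
  tibble(n_traits = nrow(x$loadings), n_genotypes = nrow(x$scores),
         n_retained = x$n_retained,
         cumulative_retained = x$eigenvalues$cumulative[x$n_retained],
         rank_deficient = x$rank_deficient)
}

#' Biplot coordinates for two components
#'
#' Genotype points are their scores on the chosen components; trait arrows
#' are the loadings scaled by the square root of the eigenvalue, so arrow
#' angles approximate trait correlations (opposite sides of the origin =
#' negative correlation).
#'
#' @param pca A [trait_pca()] result.
#' @param components Integer pair, default `c(1, 2)`.
#' @return List of tibbles `genotypes` (`genotype`, `x`, `y`) and `traits`
#'   (`trait`, `x`, `y`).
#' @export
biplot_coordinates <- function(pca, components = c(1, 2)) {
  stopifnot(inherits(pca, "trait_pca"))
  p <- nrow(pca$loadings)
  if (any(components < 1 | components > p)) {
    abort("component index out of range")
  }
  lam <- pca$eigenvalues$eigenvalue[components]
  arrows <- sweep(pca$loadings[, components, drop = FALSE], 2,
                  sqrt(lam), "*")
  list(
    genotypes = tibble(genotype = rownames(pca$scores),
                       x = unname(pca$scores[, components[1]]),
                       y = unname(pca$scores[, components[2]])),
    traits = tibble(trait = rownames(arrows),
                    x = unname(arrows[, 1]), y = unname(arrows[, 2]))
  )
}

#' Hierarchical clustering of genotypes on standardised trait means
#'
#' Euclidean distances on traits standardised to unit variance (their
#' scales differ by orders of magnitude); agglomerative clustering with
#' complete (default), average or Ward linkage; the tree is cut to exactly
#' `k` clusters and per-cluster trait means are reported on the original
#' scale.  Genotypes are processed in lexicographic order so results do
#' not depend on input row order.
#'
#' @param means Per-genotype adjusted means.
#' @param k Number of clusters.
#' @param linkage `"complete"`, `"average"` or `"ward"` (= `ward.D2`).
#' @param traits Trait columns; default all numeric.
#' @return Object of class `genotype_clusters`: `hclust` (the merge tree),
#'   `assignments` (tibble `genotype`, `cluster`), `cluster_means` (tibble,
#'   original units), `sizes`, `distance` (the `dist` object).
#' @examples
#' sim <- simulate_trial(landrace_sim_config(n_tests = 30), seed = 1)
#' cluster_genotypes(adjusted_means(sim$trial), k = 4)
#' @export
cluster_genotypes <- function(means, k = 6,
                              linkage = c("complete", "average", "ward"),
                              traits = NULL) {
  linkage <- match.arg(linkage)
  m <- means_matrix(means, traits)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  m <- m[order(rownames(m)), , drop = FALSE]
  if (k > nrow(m)) abort("domain error: k exceeds number of genotypes")
  scl <- apply(m, 2, sd)
  scl[scl == 0] <- 1
  z <- scale(m, scale = scl)
  d <- dist(z, method = "euclidean")
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- hclust(d, method = method)
  cl <- cutree(hc, k = k)
  assignments <- tibble(genotype = rownames(m), cluster = as.integer(cl))
  cm <- as_tibble(m) %>%
    mutate(cluster = as.integer(cl)) %>%
    group_by(.data$cluster) %>%
    summarise(across(dplyr::everything(), mean), .groups = "drop")
  structure(list(hclust = hc, assignments = assignments,
                 cluster_means = cm,
                 sizes = as.integer(table(cl)),
                 distance = d, linkage = linkage, k = k),
            class = "genotype_clusters")
}

#' @export
print.genotype_clusters <- function(x, ...) {
  cat("Hierarchical clustering (", x$linkage, " linkage), k = ", x$k,
      "\n  cluster sizes: ", paste(x$sizes, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.genotype_clusters <- function(x, ...) x$assignments

#' @exportS3Method generics::glance
glance.genotype_clusters <- function(x, ...) {
  tibble(k = x$k, linkage = x$linkage,
         n_genotypes = nrow(x$assignments),
         min_size = min(x$sizes), max_size = max(x$sizes))
}

#' Cluster traits by their standardised profiles
#'
#' Transposes the standardised genotype-by-trait matrix and reuses
#' [cluster_genotypes()]'s machinery, grouping traits that co-vary across
#' the collection (the horizontal dendrogram of a clustered heatmap).
#'
#' @inheritParams cluster_genotypes
#' @return A `genotype_clusters` object whose units are traits.
#' @export
cluster_traits <- function(means, k = 4,
                           linkage = c("complete", "average", "ward"),
                           traits = NULL) {
  linkage <- match.arg(linkage)
  m <- means_matrix(means, traits)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  scl <- apply(m, 2, sd)
  scl[scl == 0] <- 1
  z <- t(scale(m, scale = scl))
  tm <- as_tibble(z, rownames = "genotype")  # rows are traits here
  cluster_genotypes(tm, k = k, linkage = linkage)
}
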