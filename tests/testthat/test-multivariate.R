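means_fixture <- function(seed = 1, n_tests = 40) {
  sim <- simulate_trial(landrace_sim_config(n_tests = n_tests), seed = seed)
  adjusted_means(sim$trial)
}

test_that("self- and perfect correlations behave as expected", {
  m <- tibble::tibble(genotype = letters[1:10], x = 1:10,
                      y = 2 * (1:10), z = rnorm(10))
  cr <- trait_correlations(m)
  expect_equal(diag(cr$r), c(x = 1, y = 1, z = 1))
  expect_equal(cr$r["x", "y"], 1)
  expect_equal(cr$r, t(cr$r))
  expect_equal(cr$p.value, t(cr$p.value))
  expect_true(all(abs(cr$r) <= 1 + 1e-12))
})

test_that("sample correlation is near truth for simulated bivariate data", {
  set.seed(99)
  rr <- replicate(300, {
    z <- matrix(rnorm(103 * 2), ncol = 2)
    x <- z[, 1]
    y <- 0.7 * z[, 1] + sqrt(1 - 0.49) * z[, 2]
    cor(x, y)
  })
  expect_equal(mean(rr), 0.70, tolerance = 0.01)
  # and the package p-value matches cor.test
  m <- means_fixture(3)
  cr <- trait_correlations(m, c("PH", "FW", "YP"))
  ct <- cor.test(m$PH, m$FW)
  expect_equal(cr$r["PH", "FW"], unname(ct$estimate), tolerance = 1e-10)
  expect_equal(cr$p.value["PH", "FW"], ct$p.value, tolerance = 1e-10)
})

test_that("constant traits are flagged and their pairs left undefined", {
  m <- tibble::tibble(genotype = letters[1:5], x = 1:5, k = rep(2, 5))
  expect_warning(cr <- trait_correlations(m), "constant")
  expect_true(is.na(cr$r["x", "k"]))
  expect_equal(cr$constant, "k")
})

test_that("correlation matrix is positive semi-definite", {
  cr <- trait_correlations(means_fixture(5))
  ev <- eigen(cr$r, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("two-trait PCA has closed-form eigenvalues 1 + r and 1 - r", {
  m <- means_fixture(7)
  r <- cor(m$PH, m$FW)
  pc <- trait_pca(m, c("PH", "FW"))
  expect_equal(pc$eigenvalues$eigenvalue, c(1 + abs(r), 1 - abs(r)),
               tolerance = 1e-10)
})

test_that("eigenvalues sum to the trait count; identity gives all ones", {
  pc <- trait_pca(means_fixture(2))
  expect_equal(sum(pc$eigenvalues$eigenvalue), 17, tolerance = 1e-8)
  expect_equal(pc$eigenvalues$cumulative[17], 100, tolerance = 1e-8)
  # orthonormal loadings
  expect_equal(crossprod(pc$loadings), diag(17), tolerance = 1e-8,
               ignore_attr = TRUE)
  # near-independent traits: eigenvalues near 1
  set.seed(4)
  ind <- tibble::tibble(genotype = sprintf("g%04d", 1:5000))
  for (j in 1:4) ind[[paste0("t", j)]] <- rnorm(5000)
  pci <- trait_pca(ind)
  expect_equal(pci$eigenvalues$eigenvalue, rep(1, 4), tolerance = 0.1)
})

test_that("PCA reconstructs the standardised data", {
  m <- means_fixture(3)
  pc <- trait_pca(m)
  x <- as.matrix(m[, rownames(pc$loadings)])
  z <- scale(x, center = pc$center, scale = pc$scale)
  expect_equal(pc$scores %*% t(pc$loadings), z, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("sign convention puts each component's largest loading positive", {
  pc <- trait_pca(means_fixture(8))
  for (j in seq_len(ncol(pc$loadings))) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, j])), j], 0)
  }
})

test_that("biplot coordinates project scores and scale loadings", {
  pc <- trait_pca(means_fixture(9))
  bc <- biplot_coordinates(pc, c(1, 2))
  expect_equal(bc$genotypes$x, unname(pc$scores[, 1]))
  lam <- pc$eigenvalues$eigenvalue[1]
  expect_equal(bc$traits$x, unname(pc$loadings[, 1] * sqrt(lam)))
  expect_error(biplot_coordinates(pc, c(1, 99)), "out of range")

  # negatively correlated traits sit on opposite sides of the origin
  m <- tibble::tibble(genotype = sprintf("g%02d", 1:30), a = 1:30)
  m$b <- -m$a + rnorm(30, sd = 0.01)
  pc2 <- trait_pca(m)
  bc2 <- biplot_coordinates(pc2)
  expect_lt(bc2$traits$x[1] * bc2$traits$x[2], 0)
})

test_that("distances match a brute-force pairwise computation", {
  m <- means_fixture(4, n_tests = 17)
  cl <- cluster_genotypes(m, k = 3)
  x <- as.matrix(m[, setdiff(names(m), c("genotype", "role"))])
  rownames(x) <- m$genotype
  x <- x[order(rownames(x)), ]
  z <- scale(x)
  d_brute <- matrix(0, nrow(z), nrow(z))
  for (i in seq_len(nrow(z))) for (j in seq_len(nrow(z))) {
    d_brute[i, j] <- sqrt(sum((z[i, ] - z[j, ])^2))
  }
  expect_equal(as.matrix(cl$distance), d_brute, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("clustering is invariant to genotype input order", {
  m <- means_fixture(6, n_tests = 25)
  cl1 <- cluster_genotypes(m, k = 4)
  m2 <- m[sample(nrow(m)), ]
  cl2 <- cluster_genotypes(m2, k = 4)
  expect_equal(cl1$assignments, cl2$assignments)
  expect_equal(cl1$cluster_means, cl2$cluster_means)
})

test_that("identical genotypes merge first; k = n isolates everyone", {
  m <- tibble::tibble(genotype = c("a", "b", "c", "d"),
                      x = c(1, 1, 5, 9), y = c(2, 2, 6, 1))
  cl <- cluster_genotypes(m, k = 3)
  a_cl <- cl$assignments$cluster[cl$assignments$genotype == "a"]
  b_cl <- cl$assignments$cluster[cl$assignments$genotype == "b"]
  expect_equal(a_cl, b_cl)
  expect_equal(min(as.matrix(cl$distance)["a", "b"]), 0)

  cln <- cluster_genotypes(m, k = 4)
  expect_equal(sort(unique(cln$assignments$cluster)), 1:4)
  expect_error(cluster_genotypes(m, k = 5), "domain error")
})

test_that("size-weighted cluster means recompose the grand mean", {
  m <- means_fixture(11, n_tests = 30)
  cl <- cluster_genotypes(m, k = 5)
  w <- cl$sizes / sum(cl$sizes)
  for (tr in c("PH", "FW", "YP")) {
    grand <- mean(m[[tr]])
    recomposed <- sum(w * cl$cluster_means[[tr]])
    expect_equal(recomposed, grand, tolerance = 1e-9)
  }
})

test_that("linkage heights are non-decreasing for supported methods", {
  m <- means_fixture(13, n_tests = 20)
  for (lk in c("complete", "average", "ward")) {
    cl <- cluster_genotypes(m, k = 3, linkage = lk)
    expect_true(all(diff(cl$hclust$height) > -1e-12))
  }
})

test_that("trait clustering groups co-varying traits", {
  m <- means_fixture(15, n_tests = 60)
  ct <- cluster_traits(m, k = 4)
  expect_equal(nrow(ct$assignments), 17)
  expect_equal(length(unique(ct$assignments$cluster)), 4)
})
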