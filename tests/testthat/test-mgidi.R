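toy_means <- function(seed = 1, n = 10, p = 4) {
  set.seed(seed)
  m <- tibble::tibble(genotype = sprintf("g%02d", seq_len(n)))
  for (j in seq_len(p)) m[[paste0("t", j)]] <- rnorm(n, mean = 10 * j)
  m
}

test_that("rescaling is goal-directed, linear and bounded in [0, 100]", {
  m <- tibble::tibble(genotype = c("a", "b", "c"), up = c(1, 2, 3),
                      down = c(4, 6, 8))
  r <- rescale_traits(m, goals = c(up = "increase", down = "decrease"))
  expect_equal(unclass(r)[, "up"], c(a = 0, b = 50, c = 100))
  expect_equal(unclass(r)[, "down"], c(a = 100, b = 50, c = 0))
  big <- rescale_traits(toy_means(2, 50, 5))
  expect_true(all(big >= 0 & big <= 100))
  # max of an increase trait and min of a decrease trait both map to 100
  expect_equal(max(unclass(r)[, "up"]), 100)
  expect_equal(unclass(r)["a", "down"], 100)
})

test_that("constant traits are excluded from rescaling with a warning", {
  m <- tibble::tibble(genotype = c("a", "b"), x = c(1, 2), k = c(5, 5))
  expect_warning(r <- rescale_traits(m), "constant")
  expect_equal(colnames(r), "x")
})

test_that("factor model retains Kaiser factors and preserves communality", {
  r <- rescale_traits(toy_means(3, 60, 6))
  fm <- factor_model(r)
  lam <- fm$eigenvalues
  expect_equal(fm$n_factors, sum(lam >= 1))
  # rotation preserves per-trait communalities
  init_comm <- rowSums(fm$initial_loadings^2)
  expect_equal(fm$communality, init_comm, tolerance = 1e-8)
  expect_true(all(fm$communality <= 1 + 1e-8))
  expect_equal(fm$uniqueness, 1 - fm$communality)
  # varimax criterion of the rotated solution is no worse than unrotated
  vcrit <- function(a) sum(apply(a^2, 2, var))
  expect_gte(vcrit(fm$loadings), vcrit(fm$initial_loadings) - 1e-10)
})

test_that("two perfectly correlated traits load on a single full factor", {
  m <- tibble::tibble(genotype = sprintf("g%02d", 1:20), a = 1:20)
  m$b <- 2 * m$a
  r <- rescale_traits(m)
  fm <- factor_model(r)
  expect_equal(fm$n_factors, 1)
  expect_equal(unname(fm$communality), c(1, 1), tolerance = 1e-8)
})

test_that("MGIDI equals a brute-force recomputation on a toy matrix", {
  m <- toy_means(5, 10, 4)
  res <- mgidi(m)
  # independent recomputation from scratch
  x <- as.matrix(m[, -1]); rownames(x) <- m$genotype
  rng <- apply(x, 2, range)
  r <- sweep(sweep(x, 2, rng[1, ], "-"), 2, rng[2, ] - rng[1, ], "/") * 100
  ctr <- colMeans(r); scl <- apply(r, 2, sd)
  z <- scale(r, ctr, scl)
  e <- eigen(cor(z), symmetric = TRUE)
  f <- sum(e$values >= 1)
  v <- e$vectors[, 1:f, drop = FALSE]
  for (j in seq_len(f)) if (v[which.max(abs(v[, j])), j] < 0) v[, j] <- -v[, j]
  a <- sweep(v, 2, sqrt(e$values[1:f]), "*")
  if (f > 1) a <- unclass(stats::varimax(a, normalize = FALSE,
                                         eps = 1e-6)$loadings)
  proj <- a %*% solve(crossprod(a))
  sc <- z %*% proj
  ideo <- drop(((100 - ctr) / scl) %*% proj)
  d_brute <- sqrt(rowSums(sweep(sc, 2, ideo)^2))
  got <- res$index
  expect_equal(setNames(got$mgidi, got$genotype)[names(d_brute)],
               d_brute, tolerance = 1e-10)
})

test_that("a genotype matching the ideotype has index zero", {
  m <- toy_means(6, 12, 3)
  # make g01 the best on every trait
  for (tr in c("t1", "t2", "t3")) m[[tr]][1] <- max(m[[tr]]) + 1
  res <- mgidi(m)
  # rescaled row of g01 is all 100 -> distance 0
  expect_equal(res$index$mgidi[res$index$genotype == "g01"], 0,
               tolerance = 1e-10)
  expect_equal(res$index$rank[res$index$genotype == "g01"], 1)
})

test_that("factor contributions sum to one for every genotype", {
  res <- mgidi(toy_means(7, 30, 6))
  expect_equal(unname(rowSums(res$contributions)),
               rep(1, 30), tolerance = 1e-9)
})

test_that("single-factor ranking is the absolute score deviation order", {
  m <- tibble::tibble(genotype = sprintf("g%02d", 1:15), a = rnorm(15))
  m$b <- m$a * 1.5 + 2   # one factor
  res <- mgidi(m)
  fm <- res$factor_model
  expect_equal(fm$n_factors, 1)
  dev <- abs(fm$scores[, 1] - fm$ideotype_scores[1])
  expect_equal(res$index$genotype,
               names(sort(dev)))
})

test_that("selection count uses round-half-up on the intensity", {
  m <- toy_means(8, 103, 5)
  res <- mgidi(m, intensity = 0.20)
  expect_length(res$selected, 21)    # 103 * 0.2 = 20.6 -> 21
  res10 <- mgidi(toy_means(9, 10, 5), intensity = 0.25)
  expect_length(res10$selected, 3)   # 2.5 rounds half up to 3
  expect_error(mgidi(m, intensity = 0), "intensity")
})

test_that("selecting everyone zeroes every selection differential", {
  res <- mgidi(toy_means(10, 12, 4), intensity = 1)
  expect_equal(res$differentials$sd, rep(0, 4), tolerance = 1e-12)
  expect_equal(res$differentials$sd_pct, rep(0, 4), tolerance = 1e-12)
})

test_that("a dominant genotype is selected with positive differential", {
  m <- toy_means(11, 20, 3)
  m$t1[5] <- max(m$t1) + 50   # dominant on t1
  res <- mgidi(m, intensity = 0.2)
  expect_true(m$genotype[5] %in% res$selected)
  expect_gt(res$differentials$sd_pct[res$differentials$trait == "t1"], 0)
})

test_that("reversing a trait goal flips its expected differential", {
  set.seed(21)
  m <- tibble::tibble(genotype = sprintf("g%02d", 1:40),
                      yield = rnorm(40, 100, 10))
  m$earliness <- 200 - m$yield + rnorm(40, sd = 1)
  up <- mgidi(m, goals = c(yield = "increase", earliness = "increase"),
              intensity = 0.25)
  dn <- mgidi(m, goals = c(yield = "increase", earliness = "decrease"),
              intensity = 0.25)
  sd_up <- up$differentials$sd[up$differentials$trait == "earliness"]
  sd_dn <- dn$differentials$sd[dn$differentials$trait == "earliness"]
  expect_gt(sd_up, 0)
  expect_lt(sd_dn, 0)
})

test_that("MGIDI is invariant to positive rescaling of an input trait", {
  m <- toy_means(12, 25, 4)
  m2 <- m
  m2$t2 <- m2$t2 * 37.5
  r1 <- mgidi(m)$index
  r2 <- mgidi(m2)$index
  expect_equal(r1$mgidi, r2$mgidi, tolerance = 1e-10)
  expect_equal(r1$genotype, r2$genotype)
})

test_that("expected gain column appends when heritabilities are supplied", {
  res <- mgidi(toy_means(13, 15, 3), intensity = 0.3)
  h2 <- c(t1 = 80, t2 = 50, t3 = 20)
  d <- selection_differentials(res, h2 = h2)
  expect_equal(d$gain_pct, d$sd_pct * h2[d$trait] / 100,
               ignore_attr = TRUE)
})
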