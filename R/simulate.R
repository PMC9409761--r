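#' Simulation configuration for an augmented trial
#'
#' Defines the generative model
#' \deqn{y_{ij} = \mu + g_i + \beta_j + \varepsilon_{ij}}
#' with test-entry genotypic effects \eqn{g_i \sim N(0, \Sigma_g)}
#' (multivariate over traits), iid block effects
#' \eqn{\beta_j \sim N(0, \sigma_b^2)} per trait, plot errors
#' \eqn{\varepsilon \sim N(0, \Sigma_e)} independently per plot, and fixed
#' (non-random) deviations for the replicated checks.
#'
#' @param traits A trait dictionary ([trait_dictionary()]) or character
#'   vector of abbreviations.
#' @param trait_means Numeric vector \eqn{\mu}, one per trait.
#' @param genetic_cov Genetic covariance matrix \eqn{\Sigma_g} (positive
#'   semi-definite), or a vector of genetic variances (diagonal).
#' @param error_cov Error covariance matrix \eqn{\Sigma_e} (positive
#'   definite), or a vector of error variances.
#' @param n_blocks,n_checks,n_tests Design dimensions (b, c, n).
#' @param block_sd Block-effect standard deviation(s), length 1 or one per
#'   trait; `>= 0`.
#' @param check_effects Fixed check deviations: matrix `n_checks x n_traits`
#'   (default all zero).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(traits, trait_means, genetic_cov, error_cov,
                       n_blocks = 4, n_checks = 3, n_tests = 100,
                       block_sd = 0, check_effects = NULL) {
  if (is.character(traits)) traits <- trait_dictionary(traits)
  p <- nrow(traits)
  if (length(trait_means) != p) abort("config error: trait_means length mismatch")
  as_cov <- function(m, what, pd = FALSE) {
    if (is.null(dim(m))) m <- diag(m, nrow = length(m))
    m <- as.matrix(m)
    if (!all(dim(m) == p)) abort(paste0("config error: ", what, " dimension mismatch"))
    if (max(abs(m - t(m))) > 1e-8) abort(paste0("config error: ", what, " not symmetric"))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    tol <- 1e-8 * max(abs(ev), 1)
    if (pd && min(ev) <= tol) abort(paste0("config error: ", what, " not positive definite"))
    if (!pd && min(ev) < -tol) abort(paste0("config error: ", what, " not positive semi-definite"))
    m
  }
  genetic_cov <- as_cov(genetic_cov, "genetic_cov", pd = FALSE)
  error_cov <- as_cov(error_cov, "error_cov", pd = TRUE)
  block_sd <- rep_len(block_sd, p)
  if (any(block_sd < 0)) abort("config error: block_sd must be >= 0")
  if (is.null(check_effects)) check_effects <- matrix(0, n_checks, p)
  check_effects <- as.matrix(check_effects)
  if (!all(dim(check_effects) == c(n_checks, p))) {
    abort("config error: check_effects must be n_checks x n_traits")
  }
  if (n_blocks < 2 || n_checks < 2 || n_tests < 1) {
    abort("config error: need n_blocks >= 2, n_checks >= 2, n_tests >= 1")
  }
  structure(list(traits = traits, trait_means = as.numeric(trait_means),
                 genetic_cov = genetic_cov, error_cov = error_cov,
                 n_blocks = n_blocks, n_checks = n_checks,
                 n_tests = n_tests, block_sd = block_sd,
                 check_effects = check_effects),
            class = "sim_config")
}

# draw n rows from N(0, sigma) via the (pivoted) Cholesky factor; handles
# PSD matrices with zero eigenvalues
rmvn <- function(n, sigma) {
  p <- ncol(sigma)
  e <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  z <- matrix(rnorm(n * p), n, p)
  z %*% (t(e$vectors) * sqrt(lam))
}

#' Simulate an augmented-RCBD trial with known truth
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the same config and seed reproduce the trial
#'   bitwise.
#' @return A list with `trial` (an [augmented_trial()]) and `truth`, a
#'   tibble of per-trait ground-truth parameters (`var_g`, `var_e`,
#'   `var_block`, `h2_true` \eqn{= \sigma^2_g/(\sigma^2_g+\sigma^2_e)});
#'   the genetic correlation matrix is attached as attribute
#'   `genetic_cor`.
#' @export
simulate_trial <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  p <- nrow(config$traits)
  b <- config$n_blocks; cc <- config$n_checks; n <- config$n_tests
  abbr <- config$traits$abbr

  width <- function(n) max(2L, nchar(as.character(n)))
  blocks <- sprintf("B%0*d", width(b), seq_len(b))
  checks <- sprintf("C%0*d", width(cc), seq_len(cc))
  tests  <- sprintf("G%0*d", width(n), seq_len(n))

  g_test <- rmvn(n, config$genetic_cov)                     # n x p
  beta <- vapply(config$block_sd, function(s) rnorm(b, 0, s),
                 numeric(b))                                # b x p
  test_block <- rep_len(seq_len(b), n)                      # balanced spread

  mu <- config$trait_means
  rows <- vector("list", b)
  for (j in seq_len(b)) {
    e_chk <- rmvn(cc, config$error_cov)
    y_chk <- sweep(config$check_effects + e_chk, 2, mu + beta[j, ], "+")
    chk <- as_tibble(setNames(as.data.frame(y_chk), abbr))
    chk <- dplyr::bind_cols(tibble(block = blocks[j], genotype = checks,
                                   role = "check"), chk)
    idx <- which(test_block == j)
    e_tst <- rmvn(length(idx), config$error_cov)
    y_tst <- sweep(g_test[idx, , drop = FALSE] + e_tst, 2,
                   mu + beta[j, ], "+")
    tst <- as_tibble(setNames(as.data.frame(y_tst), abbr))
    tst <- dplyr::bind_cols(tibble(block = blocks[j], genotype = tests[idx],
                                   role = "test"), tst)
    rows[[j]] <- dplyr::bind_rows(chk, tst)
  }
  plots <- dplyr::bind_rows(rows)

  var_g <- unname(diag(config$genetic_cov))
  var_e <- unname(diag(config$error_cov))
  truth <- tibble(abbr = abbr, var_g = var_g, var_e = var_e,
                  var_block = config$block_sd^2,
                  h2_true = ifelse(var_g + var_e > 0,
                                   var_g / (var_g + var_e), NA_real_))
  attr(truth, "genetic_cor") <- stats::cov2cor(
    config$genetic_cov + diag(1e-12, p))
  list(trial = augmented_trial(plots, config$traits), truth = truth)
}

#' Simulate a coded qualitative table
#'
#' Draws each genotype's state independently from the descriptor's state
#' probabilities (iid multinomial).
#'
#' @param frequencies Named list: descriptor name -> named numeric vector
#'   of state probabilities, names = state codes; each must sum to 1
#'   (within 1e-9) and be non-negative.
#' @param descriptors A descriptor dictionary covering every descriptor in
#'   `frequencies` (defines `k`, the number of defined states); `NULL`
#'   builds a minimal dictionary from the frequency codes.
#' @param n_genotypes Number of genotypes to draw.
#' @param seed Integer seed.
#' @return A [qualitative_table()].
#' @export
simulate_qualitative <- function(frequencies, n_genotypes = 103,
                                 descriptors = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  for (d in names(frequencies)) {
    pr <- frequencies[[d]]
    if (any(pr < 0)) abort(paste0("config error: negative probability for ", d))
    if (abs(sum(pr) - 1) > 1e-9) {
      abort(paste0("config error: probabilities for ", d, " do not sum to 1"))
    }
  }
  if (is.null(descriptors)) {
    descriptors <- descriptor_dictionary(
      names(frequencies),
      purrr::map(frequencies, function(pr) {
        tibble(code = as.integer(names(pr)),
               label = paste0("state", names(pr)))
      }))
  }
  gid <- sprintf("G%0*d", max(2L, nchar(as.character(n_genotypes))),
                 seq_len(n_genotypes))
  obs <- tibble(genotype = gid)
  for (d in names(frequencies)) {
    pr <- frequencies[[d]]
    codes <- as.integer(names(pr))
    # index-based draw: safe when a descriptor has a single defined state
    obs[[d]] <- codes[sample.int(length(codes), n_genotypes,
                                 replace = TRUE, prob = pr)]
  }
  qualitative_table(obs, descriptors[match(names(frequencies),
                                           descriptors$name), ])
}

#' Default cucumber descriptor dictionary (17 descriptors)
#'
#' Defined states for the standard qualitative cucumber descriptors, coded
#' per the crop's minimal descriptor list.  `k` (defined states) drives the
#' Shannon-Weaver normalisation even when a collection does not express
#' every state.
#'
#' @return A descriptor dictionary tibble.
#' @export
cucumber_descriptors <- function() {
  s <- function(codes, labels) tibble(code = as.integer(codes), label = labels)
  descriptor_dictionary(
    name = c("Plant growth type", "Plant growth habit", "Stem colour",
             "Stem pubescence density", "Leaf intensity of green colour",
             "Leaf blade shape", "Leaf apex shape", "Leaf pubescence density",
             "Flower colour", "Sex type", "Stem end fruit shape",
             "Blossom end fruit shape", "Fruit skin texture", "Fruit shape",
             "Fruit skin colour (table maturity)",
             "Fruit skin colour (mature harvest)", "Seed colour"),
    states = list(
      s(c(1, 3), c("Determinate", "Indeterminate")),
      s(c(1, 3, 5), c("Viny", "Intermediate", "Prostrate")),
      s(1:3, c("Light green", "Green", "Dark green")),
      s(1:3, c("Dense", "Intermediate", "Sparse")),
      s(c(1, 3, 5), c("Light", "Medium", "Dark")),
      s(1:4, c("Orbicular", "Sagittate", "Reniform", "Cordate")),
      s(c(1, 3), c("Obtuse", "Rounded")),
      s(1:3, c("Dense", "Intermediate", "Sparse")),
      s(1:2, c("White", "Yellow")),
      s(c(0, 1, 3, 5), c("Monoecious", "Hermaphroditic", "Androecious",
                         "Gynoecious")),
      s(c(0, 1, 3), c("Necked", "Acute", "Obtuse")),
      s(c(1, 2, 9), c("Flat", "Deep raised", "Other")),
      s(0:1, c("Smooth", "Wrinkled")),
      s(1:5, c("Oblong", "Oval", "Ellipsoid", "Blossom end tapered",
               "Ovate")),
      s(1:7, c("Light green", "Green", "Dark green", "Yellowish green",
               "Greenish yellow", "Blackish green", "Whitish green")),
      s(1:2, c("Brown", "Yellow")),
      s(1:2, c("White", "Cream"))
    ))
}

#' Reference state frequencies for the cucumber descriptor set
#'
#' Observed state frequencies of 103 Bangladeshi cucumber landraces
#' (checks included), used as simulator defaults: e.g. seed colour
#' 43 white / 60 cream, monomorphic plant growth type.
#'
#' @return Named list of per-descriptor probability vectors (names =
#'   state codes).
#' @export
cucumber_descriptor_frequencies <- function() {
  f <- function(codes, counts) setNames(counts / sum(counts),
                                        as.character(codes))
  list(
    "Plant growth type"        = f(3, 103),
    "Plant growth habit"       = f(c(1, 3), c(94, 9)),
    "Stem colour"              = f(1:3, c(4, 73, 26)),
    "Stem pubescence density"  = f(1:2, c(61, 42)),
    "Leaf intensity of green colour" = f(c(1, 3, 5), c(53, 41, 9)),
    "Leaf blade shape"         = f(1, 103),
    "Leaf apex shape"          = f(c(1, 3), c(72, 31)),
    "Leaf pubescence density"  = f(1, 103),
    "Flower colour"            = f(2, 103),
    "Sex type"                 = f(0, 103),
    "Stem end fruit shape"     = f(c(0, 1, 3), c(1, 30, 72)),
    "Blossom end fruit shape"  = f(1:2, c(100, 3)),
    "Fruit skin texture"       = f(0:1, c(31, 72)),
    "Fruit shape"              = f(c(1, 2, 3, 5), c(87, 5, 4, 7)),
    "Fruit skin colour (table maturity)" = f(1:7, c(67, 15, 4, 13, 2, 1, 1)),
    "Fruit skin colour (mature harvest)" = f(1:2, c(72, 31)),
    "Seed colour"              = f(1:2, c(43, 60))
  )
}

# per-trait calibration for the default landrace simulator: trait means and
# genotypic/error variances on the scale of a 103-entry cucumber landrace
# trial (17 traits); DFM and FFH carry low heritability (their accession
# mean squares fall at or below error), modelled with small positive
# genetic variance so the covariance stays well-conditioned
landrace_calibration <- function() {
  tibble(
    abbr = c("PH", "BPP", "DI", "DM", "DFM", "NMF", "NMFF", "LN", "LW",
             "FFH", "FL", "FD", "FW", "NFP", "DH", "YP", "HSW"),
    mean = c(221.00, 4.60, 7.44, 39.11, 47.59, 5.78, 9.91, 14.01, 17.38,
             59.76, 17.53, 5.91, 298.60, 5.41, 85.59, 1.93, 2.68),
    var_g = c(1423.59, 0.40, 3.93, 4.75, 1.00, 0.31, 0.65, 4.28, 6.06,
              1.00, 11.48, 0.65, 7551.91, 2.07, 15.07, 0.35, 0.11),
    var_e = c(84.28, 0.08, 0.34, 6.31, 18.42, 0.95, 1.08, 0.91, 1.55,
              14.92, 1.62, 0.23, 482.59, 0.37, 2.97, 0.04, 0.03)
  )
}

# block-diagonal genetic correlation over the four trait groups a trait
# dendrogram of such trials recovers: phenology, vigour/yield, fruit size,
# leaf/internode
landrace_genetic_cor <- function(abbr, rho = 0.5) {
  groups <- list(c("DH", "FFH", "DFM", "DM", "NMFF", "NMF"),
                 c("PH", "YP", "NFP", "BPP"),
                 c("HSW", "FL", "FD", "FW"),
                 c("LN", "LW", "DI"))
  r <- diag(length(abbr))
  dimnames(r) <- list(abbr, abbr)
  for (g in groups) {
    g <- intersect(g, abbr)
    r[g, g] <- rho
  }
  diag(r) <- 1
  r
}

#' Calibrated cucumber landrace trial configuration
#'
#' The default study conditions: 4 blocks, 3 checks, 100 unreplicated test
#' entries (112 plots), 17 quantitative traits with means and
#' genotypic/error variances calibrated to a large Bangladeshi cucumber
#' landrace evaluation; genetic correlations are block-structured over the
#' four empirical trait groups (within-group 0.5).  Block standard
#' deviation defaults to half the error SD per trait (block effects small,
#' as such trials report).
#'
#' @param n_blocks,n_checks,n_tests Design dimensions.
#' @param rho Within-group genetic correlation.
#' @param block_sd_frac Block SD as a fraction of the error SD.
#' @return A [sim_config()].
#' @export
landrace_sim_config <- function(n_blocks = 4, n_checks = 3, n_tests = 100,
                                rho = 0.5, block_sd_frac = 0.5) {
  cal <- landrace_calibration()
  traits <- cucumber_traits()
  cal <- cal[match(traits$abbr, cal$abbr), ]
  sg <- sqrt(cal$var_g)
  cor_g <- landrace_genetic_cor(traits$abbr, rho)
  sigma_g <- outer(sg, sg) * cor_g
  sim_config(traits = traits, trait_means = cal$mean,
             genetic_cov = sigma_g, error_cov = diag(cal$var_e),
             n_blocks = n_blocks, n_checks = n_checks, n_tests = n_tests,
             block_sd = block_sd_frac * sqrt(cal$var_e))
}

#' Complete synthetic landrace data set
#'
#' Generates the quantitative trial and the qualitative table under one
#' seed, at the default study conditions (103 genotypes, 4 blocks, 3
#' checks, 17 traits, 17 descriptors).
#'
#' @param seed Integer seed.
#' @return List with `trial`, `truth` and `qualitative`.
#' @export
landrace_fixture <- function(seed = 1L) {
  sim <- simulate_trial(landrace_sim_config(), seed = seed)
  qual <- simulate_qualitative(cucumber_descriptor_frequencies(),
                               n_genotypes = 103,
                               descriptors = cucumber_descriptors(),
                               seed = seed + 1L)
  # align qualitative genotype ids with the trial's checks + tests
  ids <- c(sim$trial$checks, sim$trial$tests)
  qual$observations$genotype <- sort(ids)
  qual <- qualitative_table(qual$observations, qual$descriptors)
  list(trial = sim$trial, truth = sim$truth, qualitative = qual)
}
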