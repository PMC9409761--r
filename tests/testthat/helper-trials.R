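# Shared fixtures and independent oracles for the test suite.

# Hand-sized trial: 2 blocks, 2 checks, 2 tests, one trait.
# Check values chosen so block effects are (-2, +2) by hand computation.
tiny_trial <- function(test_values = c(50, 47)) {
  plots <- tibble::tibble(
    block = c("B1", "B1", "B2", "B2", "B1", "B2"),
    genotype = c("C1", "C2", "C1", "C2", "T1", "T2"),
    role = c(rep("check", 4), rep("test", 2)),
    PH = c(10, 12, 14, 16, test_values)
  )
  augmented_trial(plots)
}

# Small random trial with a single trait for oracle comparisons.
random_trial <- function(seed, n_blocks = 3, n_checks = 3, n_tests = 12,
                         var_g = 4, var_e = 1, block_sd = 2) {
  cfg <- sim_config("Y", trait_means = 10,
                    genetic_cov = matrix(var_g, 1, 1),
                    error_cov = matrix(var_e, 1, 1),
                    n_blocks = n_blocks, n_checks = n_checks,
                    n_tests = n_tests, block_sd = block_sd)
  simulate_trial(cfg, seed = seed)$trial
}

# OLS oracle: genotype coefficients of y ~ 0 + genotype + block with
# sum-to-zero block contrasts equal the block-adjusted genotype means.
ols_adjusted_means <- function(trial, trait) {
  d <- trial$plots
  d <- d[!is.na(d[[trait]]), ]
  d$genotype <- factor(d$genotype)
  d$block <- factor(d$block)
  fml <- stats::as.formula(paste(trait, "~ 0 + genotype + block"))
  fit <- stats::lm(fml, data = d,
                   contrasts = list(block = "contr.sum"))
  cf <- stats::coef(fit)
  g <- cf[startsWith(names(cf), "genotype")]
  names(g) <- sub("^genotype", "", names(g))
  g
}

# OLS oracle for the residual mean square of the genotype + block fit.
ols_residual_ms <- function(trial, trait) {
  d <- trial$plots
  d$genotype <- factor(d$genotype)
  d$block <- factor(d$block)
  fml <- stats::as.formula(paste(trait, "~ genotype + block"))
  fit <- stats::lm(fml, data = d)
  sum(stats::resid(fit)^2) / fit$df.residual
}
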