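Package: phenodiv
Title: Phenotypic Divergence Analysis of Germplasm Collections from
    Augmented Block Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses phenotypic divergence in crop germplasm collections
    evaluated in augmented randomised complete block designs, where
    replicated check varieties estimate block effects and experimental
    error for a large set of unreplicated test entries.  Provides the
    Federer block adjustment and treatment-adjusted analysis of variance,
    quantitative-genetic variability parameters (genotypic and phenotypic
    coefficients of variation, broad-sense heritability, genetic advance
    under truncation selection), normalised Shannon-Weaver diversity
    indices for coded qualitative descriptors, correlation, principal
    component and hierarchical cluster analyses of adjusted genotype
    means, and the multi-trait genotype-ideotype distance index (MGIDI)
    with varimax-rotated factor analysis and selection differentials.
    A calibrated trial simulator with known ground-truth variance
    components supports parameter-recovery validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    grid,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
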