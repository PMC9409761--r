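---
title: "Methods: augmented-trial divergence analysis in phenodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: augmented-trial divergence analysis in phenodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodiv)
```

`phenodiv` analyses phenotypic divergence in germplasm collections grown
in augmented randomised complete block designs. This vignette is the
package's account of the statistical machinery: the models, the
estimators, the numerical conventions, and — just as important — what
the validation on synthetic trials does and does not demonstrate.

## The design and its model

An augmented RCBD grows `c` replicated check varieties in each of `b`
blocks and `n` unreplicated test entries, each in exactly one block
(`b·c + n` plots). The working model for a plot value is additive:

$$y_{ij} = \mu + g_i + \beta_j + \varepsilon_{ij},$$

with genotype effect $g_i$, block effect $\beta_j$ and independent plot
error $\varepsilon_{ij} \sim N(0, \sigma^2_e)$. Because only the checks
are replicated, block effects are estimable from them alone:

$$\hat\beta_j = \bar y_{\text{checks}, j} - \bar y_{\text{checks}},$$

which sum to zero by construction. A test entry's adjusted mean is its
single observation minus its block's estimated effect; a check's
adjusted mean is its plain average over the `b` blocks (block effects
cancel there). These adjusted means are exactly the genotype estimates
of an ordinary least-squares fit of `genotype + block` to all plots —
the test suite asserts this equivalence to 1e-8 against `lm()` on
randomly generated trials.

### The ANOVA partition

`augmented_anova()` reports Block, Treatment, the treatment partition
(Check, Accession, Accession vs Check), and the Residual with
`(b-1)(c-1)` degrees of freedom estimated from the check-by-block
interaction. Two conventions deserve explanation:

* **The treatment partition is computed by exact sequential least
  squares** (blocks first, then the check/test group contrast, then
  check identities, with the test identities absorbing the remainder),
  not by the textbook hand formula that sums squared deviations of the
  adjusted test values. The two differ: adjusted values share the
  estimation error of their block's effect, so the hand formula's
  accession mean square has expectation $\sigma^2_e(1 + \delta)$ with
  $\delta \approx 0.25$ at `b = 4, c = 3`, inflating the F-test's
  type-I error to roughly 0.09. The sequential partition is the one an
  `aov()`/`lm()` analysis produces; under it the accession F-test holds
  its nominal size (measured 0.052 over 1000 null simulations in the
  acceptance suite) and the residual mean square is identical to the
  OLS residual. Check SS is unaffected (checks are orthogonal to
  blocks), and SS additivity of the partition holds by construction.
* **The Block row is the checks-based block sum of squares** on `b - 1`
  df. Blocks and treatments are not orthogonal in this design, so a
  block line can be defined several ways; the checks-based line is the
  one the block-adjustment itself uses. It feeds no downstream
  estimator.

Significance codes are `**` (p ≤ 0.01), `*` (p ≤ 0.05), `ns`
otherwise, with no multiplicity correction across traits — the
convention of the characterisation literature this package serves. A
trial with zero variation returns a structured degenerate result (all
SS 0, F and p `NA`) rather than NaNs.

## Variability parameters

From the accession mean square (MSG) and residual mean square (MSE):

$$\hat\sigma^2_g = \max(0,\, \text{MSG} - \text{MSE}), \qquad
  \hat\sigma^2_p = \hat\sigma^2_g + \text{MSE},$$

$$\text{GCV} = \frac{100\,\hat\sigma_g}{\bar X}, \quad
  \text{PCV} = \frac{100\,\hat\sigma_p}{\bar X}, \quad
  h^2 = \frac{100\,\hat\sigma^2_g}{\hat\sigma^2_p}, \quad
  \text{GA} = k\, h^2 \hat\sigma_p,$$

with GAM = 100·GA/X̄ and $\bar X$ the mean of the adjusted genotype
means. Negative $\hat\sigma^2_g$ is floored at zero and flagged
(`floored = TRUE`), the standard practice when MSG falls below MSE.

Parameters that matter:

* **`k` — selection-intensity constant**, dimensionless, default
  **2.063**, the standardised selection differential at a 5% selected
  fraction. The common rounded value 2.06 changes GA in the second
  decimal (e.g. 173.6 vs 173.8 on a fruit-weight-scaled trait);
  2.063 is the value that makes published variability tables
  internally consistent to two decimals, and it is configurable
  everywhere it appears.
* **Category bands**: GCV, PCV and GAM are labelled L (<10%),
  M (10–20%), H (>20%) — the Sivasubramanian–Madhavamenon bands — and
  h² is labelled L (0–30%), M (30–60%), H (>60%). These reproduce every
  published letter code we can re-derive from printed mean squares.

An internal-consistency identity worth knowing: $h^2 =
100\,(\text{GCV}/\text{PCV})^2$ exactly, so any two of the three columns
determine the third; the test suite asserts it.

## Shannon–Weaver diversity

For a qualitative descriptor observed in states with proportions
$p_i$, the raw index is $H' = -\sum_i p_i \ln p_i$ (with
$0 \ln 0 := 0$) and the normalised index divides by $\ln k$, where **k
counts the states defined in the descriptor dictionary, not the states
observed**. A two-state descriptor whose dictionary defines three
states normalises by ln 3. This is why the descriptor dictionary is a
first-class input: the same observed counts yield different normalised
indices under different defined-state sets, and collections often fail
to express every defined state. A single-state descriptor (k = 1) has
index 0 by convention. Proportions are always computed from integer
counts, never from pre-rounded percentages. Higher values mean more
diversity: 0 is monomorphic, 1 a uniform spread over all defined
states.

## Multivariate analyses

All multivariate stages operate on the adjusted genotype means and
standardise traits to zero mean and unit variance first — trait scales
in such collections differ by orders of magnitude (fruit weight in
hundreds of grams against fruit diameter in centimetres), and distances
or components on raw scales would be fruit-weight analyses in disguise.

* **Correlations**: pairwise Pearson on complete cases; two-sided
  p-values from $t = r\sqrt{(n-2)/(1-r^2)}$ with `n − 2` df; stars at
  0.05 / 0.01 / 0.001.
* **PCA**: eigendecomposition of the trait correlation matrix, so
  eigenvalues sum to the trait count; components with $\lambda \ge 1$
  are retained (Kaiser). Eigenvector signs are fixed by making each
  component's largest-magnitude loading positive — a deterministic
  convention, since eigenvectors are defined only up to sign. Biplot
  trait arrows are loadings scaled by $\sqrt\lambda$.
* **Clustering**: Euclidean distance on the standardised means,
  agglomerative clustering with **complete linkage by default**
  (the default of the heatmap tooling this analysis style comes from;
  `average` and `ward` = `ward.D2` are selectable), cut to exactly `K`
  clusters; cluster means are reported back on the original trait
  scale. Genotypes are processed in lexicographic id order, making the
  result invariant to input row order. The package clusters
  genotype-level adjusted means — not plot-level records — because the
  genotype is the unit of interest in a divergence study; a plot-level
  clustering would let replicated checks appear in several clusters.
  `cluster_traits()` transposes the standardised matrix to group
  co-varying traits (the horizontal dendrogram of a clustered heatmap).

## MGIDI

The multi-trait genotype–ideotype distance index proceeds in four
steps:

1. **Goal-directed rescaling.** Each trait is linearly mapped to
   [0, 100] so that 100 is the *desirable* extreme: the maximum for
   `goal = "increase"` traits, the minimum for `goal = "decrease"`.
   The ideotype is the virtual genotype scoring 100 everywhere. The
   default goal vector marks the phenology traits (days to male/female
   flower, first and mature fruit harvest) as `decrease` — earliness is
   desirable — and everything else `increase`; it is fully
   user-overridable. Constant traits cannot be rescaled and are dropped
   with a warning.
2. **Factor analysis.** Eigendecomposition of the rescaled traits'
   correlation matrix; factors with $\lambda \ge 1$ retained; initial
   loadings $L = V_f\,\mathrm{diag}(\sqrt{\lambda_f})$; varimax
   rotation without row normalisation (tolerance 1e-6, deterministic
   start at the unrotated loadings — no random restarts, so results are
   bit-reproducible). Rotation preserves each trait's communality; the
   tests assert this to 1e-8.
3. **Scores.** Ordinary-least-squares projection
   $F = Z A (A^\top A)^{-1}$ with $Z$ the column-standardised rescaled
   matrix; the ideotype row is standardised with the genotypes' means
   and SDs and projected identically.
4. **Index and selection.**
   $\text{MGIDI}_i = \sqrt{\sum_j (\gamma_{ij} - \gamma_j)^2}$, ranked
   ascending with ties broken by genotype id. The selected count at
   intensity $\alpha$ is $\mathrm{round}(\alpha n)$ with **half-up
   rounding** (so 20% of 103 selects 21, matching breeding practice of
   rounding the selected fraction up at the margin). Factor
   contributions $\omega_{ij} = (\gamma_{ij}-\gamma_j)^2 /
   \text{MGIDI}_i^2$ sum to one per genotype and show which factor
   keeps a genotype from the ideotype; a genotype exactly at the
   ideotype (distance 0) is assigned equal contributions. Per-trait
   selection differentials are means of the selected minus means of
   all, optionally multiplied by $h^2/100$ for an expected-gain
   column.

MGIDI is invariant to positive rescaling of any input trait (the 0–100
rescaling absorbs units), which the suite checks, and it is pinned
end-to-end against an independent brute-force recomputation on a toy
matrix.

## The simulator and what validation on it shows

`simulate_trial()` draws test-entry genotype effects from
$N(0, \Sigma_g)$ (multivariate over traits), iid block effects
$N(0, \sigma^2_b)$ per trait, and plot errors from $N(0, \Sigma_e)$;
checks carry fixed (default zero) deviations rather than random
effects, consistent with fixed-check augmented-design theory. Identical
configuration and seed reproduce a trial bitwise.

The calibrated default (`landrace_sim_config()`) emulates a large
cucumber landrace evaluation: 4 blocks, 3 checks, 100 test entries (112
plots), 17 traits with collection-scale means (vine length 221 cm,
fruit weight 299 g, yield 1.93 kg/plant, …) and genotypic/error
variances chosen so heritabilities span the realistic 25–95% range. Two
phenology traits whose accession mean squares sit at or below error in
such trials are modelled with near-zero genetic variance. Genetic
correlations are block-structured over the four empirically recurring
trait groups (phenology; vigour/yield; fruit size; leaf/internode) at
within-group ρ = 0.5 — strong enough that the factor analysis recovers
a handful of interpretable factors, weak enough to keep the covariance
well-conditioned. The qualitative simulator draws iid multinomial
states per genotype at reference frequencies from a 103-accession
collection (e.g. seed colour 43:60, several monomorphic descriptors).

What the simulator does **not** emulate: spatial field trend within
blocks, genotype-by-environment structure, non-normal or heteroscedastic
errors, within-plot plant-to-plant variation (one value per plot), and
any linkage between a genotype's qualitative states and its quantitative
effects. Passing parameter-recovery tests therefore demonstrates that
the estimators are correct *under the additive model they assume*, not
that the model is adequate for any particular field data set.

### Known statistical limitations

* With the study-scale design the residual has only
  `(b-1)(c-1) = 6` degrees of freedom. The zero-floor on
  $\hat\sigma^2_g$ then skews $\hat h^2$ upward when true heritability
  is low: in our simulations mean $\hat h^2 \approx 33$ at a true 20%,
  while recovery at 50% and 80% is within ~1 point. This is intrinsic
  small-sample behaviour of the floored moment estimator, not an
  implementation artefact ($\hat\sigma^2_g$ itself is unbiased in the
  regime where the floor rarely binds, and the F-test size is nominal);
  users wanting reliable low-heritability estimates need more checks or
  blocks.
* The accession-vs-check contrast and the block line are conventions
  (documented above); other software may print slightly different
  values for those two rows while agreeing on everything downstream,
  because no estimator consumes them.
* MGIDI factor scores use the OLS projection; regression-method scores
  from a uniqueness-weighted estimator would differ slightly. The OLS
  choice keeps the index reproducible from the loadings alone.

## Problem sizes used in the validation suite

The test suite runs entirely on synthetic data generated at test time:
the study-scale fixture (112 plots, 17 traits) for end-to-end checks,
and reduced designs (2–5 blocks, 2–4 checks, 8–40 tests, one trait) for
the oracle comparisons. The simulation-based properties use 1000 null
replicates for the F-test size, 500 replicates per level for
heritability recovery, and 100 random trials for the least-squares
equivalence — sizes at which the Monte-Carlo standard errors are
comfortably inside the asserted bands.
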