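---
title: "Missing-value-tolerant batch harmonization by matrix dissection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missing-value-tolerant batch harmonization by matrix dissection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batchquilt)
```

## Why dissection

Combining independently acquired proteomic or metabolomic runs produces a
features × samples matrix in which (i) each run (batch) imposes systematic
location and scale offsets and (ii) many features are absent from entire
batches. The absence of a feature from a whole batch is tied to the
experimental setting — a different instrument, search database or labeling
chemistry — so it is *missing not at random* (MNAR), and filling such blocks
by imputation biases every downstream batch-effect estimate. Scattered
missing values within a batch (*missing at random*, MAR) are a separate,
milder phenomenon.

The strategy implemented here corrects without imputation by exploiting the
structure of what **is** observed. A batch is declared present for a feature
when the feature has at least `min_per_batch` observed values in it (default
2 — the minimum for a within-batch variance estimate; the threshold is
configurable but 1 disables scale estimation and is discouraged). Features
sharing a presence pattern form a sub-matrix over exactly the columns of
their present batches; each sub-matrix is block-complete and can be batch
corrected on its own; the corrected sub-matrices are rejoined into the
original layout. Features present in fewer than two batches cannot be
corrected and pass through verbatim.

For `n` batches the number of correctable patterns is bounded by
$t_n = \sum_{k=2}^{n} \binom{n}{k} = 2^n - n - 1$
(`max_submatrix_count()`); realized pattern counts are additionally bounded
by the number of features, and in data we simulate (and in published
multi-batch studies) sit far below the combinatorial bound.

## The correction models

### Empirical Bayes (location/scale)

For feature $g$ in batch $b$ the model is
$y_{gbj} = \alpha_g + X\beta_g + \gamma_{gb} + \delta_{gb}\,\varepsilon_{gbj}$,
$\varepsilon \sim N(0, \sigma_g^2)$. Estimation is per sub-matrix:

1. **Standardize** (`eb_standardize()`): available-case least squares gives
   batch means (plus optional covariate effects); the grand mean $\alpha_g$
   weights batch means by their observed counts, and the pooled variance
   $\sigma_g^2$ is the mean squared residual over the feature's observed
   cells (divisor $N_g$, the observed count — so a two-batch feature with
   values (1,2 | 3,4) has $\alpha = 2.5$, $\sigma^2 = 0.25$).
2. **Estimate and shrink**: $\hat\gamma_{gb}$ is the available-case batch
   mean of the standardized data and $\hat\delta^2_{gb}$ the available-case
   sample variance (divisor $n_{gb}-1$). *Parametric* mode places
   $\gamma_{gb} \sim N(\bar\gamma_b, \tau_b^2)$ with moments estimated across
   features, and $\delta^2_{gb} \sim$ Inverse-Gamma$(\lambda_b, \theta_b)$ by
   method of moments ($\lambda = \bar m^2/v + 2$, $\theta = \bar m^3/v +
   \bar m$ from the cross-feature mean $\bar m$ and variance $v$ of
   $\hat\delta^2$); the coupled posterior equations are solved by fixed-point
   iteration to relative tolerance $10^{-4}$ (maximum 500 iterations;
   non-convergence warns and uses the last iterate). *Nonparametric* mode
   computes each feature's posterior as the likelihood-weighted average of
   the **other** features' $(\hat\gamma, \hat\delta^2)$ under the normal
   likelihood of its standardized batch values — an exact deterministic
   summation, with weights accumulated in log space and the maximum
   subtracted before exponentiation so large sub-matrices do not underflow.
3. **Adjust** (`combat_adjust()`):
   $y^* = \sigma_g (z - \gamma^*_{gb}) / \delta^*_{gb} + \alpha_g +
   X\beta_g$. With `mean_only = TRUE`, $\delta^{*2} \equiv 1$ and only
   location is corrected.

Degenerate situations are handled explicitly: a sub-matrix with a single
feature has no cross-feature information, so the unshrunken estimates are
used with a warning; $\tau^2 = 0$ (all features agree on the batch location)
returns $\gamma^* = \hat\gamma$; zero cross-feature variance of
$\hat\delta^2$ makes the inverse-gamma prior undefined, so scale shrinkage
is skipped for that batch; (near-)constant features have their pooled
variance floored at $10^{-8}$ and standardize to exactly zero. Every moment
throughout is available-case: the dissection guarantees at least two values
per (feature, batch) block, not completeness, and the reference
implementations' refusal of within-batch `NA`s is precisely what this
package removes. In the posterior-mean formula the observed count $n_{gb}$
of each block is used in both the location+scale and the mean-only paths
(some implementations fix $n = 1$ in the mean-only path; we prefer the
count-consistent form). On complete data the parametric and nonparametric
adjustments agree with the reference empirical-Bayes implementation to
numerical precision (asserted in the test suite against `sva::ComBat`, which
is used only as a cross-check, never called by the package).

### Linear model

`remove_batch_linear()` fits, per feature and by available-case least
squares, an intercept + optional covariates + batch with **sum-to-zero
contrasts**, and subtracts only the fitted batch component. Sum-to-zero
encoding makes the intercept the balanced grand mean, so correction
re-centers every batch on it; the operation is idempotent and preserves
covariate (treatment) effects exactly. It agrees with
`limma::removeBatchEffect` on complete data (cross-check in the tests).

### Choosing between them

The linear model zeroes empirical batch means exactly and is preferable when
batches are large and the per-feature estimates reliable. The empirical-Bayes
corrector borrows strength across features — essential for small batches
(2–6 samples) — at the cost of leaving a small shrinkage residual in the
empirical batch means; it additionally corrects scale differences, which the
linear model does not.

## Singletons and rejoining

A feature assigned to a pattern may still hold one stray value in a batch
outside its pattern (fewer than `min_per_batch` observations). Such a value
admits no variance estimate and cannot be corrected; by default `rejoin()`
blanks it, because mixing corrected and uncorrected values on one row
misleads downstream statistics. `keep_singletons = TRUE` retains them
verbatim (and is required for exact identity round trips); the count of
discarded cells is reported. Passthrough features — present in at most one
batch — are never modified at all, singletons included.

## Parallel execution

Sub-matrix corrections are independent. `parallel_map()` schedules groups
largest-first over forked workers and re-sorts results into the
deterministic group order (lexicographic over sorted batch labels), so
outputs are bit-identical for any worker count — asserted in the tests on a
23-batch stress fixture. A group whose correction fails is passed through
unchanged and surfaced in the report, so one pathological pattern cannot
abort a run over thousands of features.

## The synthetic generator

`simulate_batches()` emulates the target data class: log2-scale abundances
with per-feature baselines ($N(25, 2^2)$), a two-phenotype effect
(`de_fraction` of features shifted by `de_log2fc` in every batch, phenotypes
balanced within batches so treatment and batch are unconfounded), additive
per-batch shifts $\gamma_b \sim N(0, \texttt{gamma\_sd}^2)$, multiplicative
per-batch scaling of the within-batch noise
$\delta_b \sim U(\texttt{delta\_range})$, MNAR as whole (feature, batch)
block dropout, and MAR as i.i.d. scattered blanking. Two generator choices
deserve explanation:

* **Scale acts on the noise term**, $y = \mu_g + \text{pheno} + \gamma_b +
  \delta_b \varepsilon$, i.e. the empirical-Bayes generative model itself.
  Scaling the raw value (baseline ≈ 25) by $\delta_b$ would mostly inject a
  second, feature-dependent location shift of ≈ $25(\delta_b - 1)$ and make
  the batch-mean difference of a null feature no longer equal the injected
  $\gamma$ difference.
* **Per-feature noise sds are log-normal** (median `noise_sd` = 0.5 log2
  units, `noise_sd_spread` = 0.5 on the log scale), matching the
  order-of-magnitude spread of replicate variability across real proteins.
  Identical variances for all features are a degenerate regime for any
  empirical-Bayes prior: the cross-feature spread of standardized batch
  locations is then pure sampling noise and the prior shrinks every estimate
  about half-way, leaving a floor of residual empirical between-batch
  variance near $0.25\,b/N$ of total. Homogeneous variances remain available
  via `noise_sd_spread = 0`.

Defaults (four batches of six, `gamma_sd` 1.5, `delta_range` 0.7–1.4,
30% MNAR, 5% MAR, 10% differential features at 1 log2 unit) describe a hard
but realistic integration scenario. The generator does **not** emulate
peptide-to-protein rollup, intensity dependence of variance, correlated
features, or instrument drift within a batch; left-censored
(intensity-dependent) missingness exists as an optional flag
(`censor_quantile`) but is off by default. Passing tests on this generator
therefore demonstrate correctness of the estimation machinery under the
stated model, not performance on any particular real acquisition.

## Evaluation statistics

* `between_batch_variance_fraction()`: per feature, one-way between-batch
  SS over total SS on available cases (batches with fewer than two observed
  values for a feature are dropped from its decomposition), averaged over
  qualifying features. Under no batch effect it approaches
  $(b-1)/(N-1)$, not 0 — compare against that null, and note that
  empirical-Bayes shrinkage leaves a small positive residual by design.
* `ttest_features()`: vectorized two-sided pooled-variance Student t (the
  convention in the field's figure legends; Welch via `var_equal = FALSE`),
  available-case, with features lacking two values per group excluded and
  counted. Agrees with `stats::t.test` to $10^{-10}$ (test-suite
  cross-check).
* CVs (`sample_stats()`, `feature_cv()`): $100\,s/\bar x$ on whatever scale
  the matrix is in. On log2 data, means near zero make the CV explode; we
  deliberately do not guess a scale — compute CVs on raw-scale intensities
  when that is what you mean.
* `nipals_pca()`: samples are observations; features are centered on
  available-case means; missing cells are skipped in the alternating
  regressions and in deflation. Convergence at relative tolerance $10^{-9}$
  or 500 iterations (warning on failure). Sign is fixed per component
  (largest-magnitude loading positive) for determinism. On complete data the
  scores match eigendecomposition PCA; explained variance is the fraction of
  total available-case SS captured by each component's rank-1 reconstruction.

## Numerical and design notes

* Missing tokens on read: the empty string, `NA`, `NaN` (case-insensitive);
  writes always use `NA`. Columns are matched to the design by sample id,
  not file position.
* All randomness is seed-controlled at the call site
  (`simulate_batches(seed=)`, `impute_downshifted_normal(seed=)`); both
  save and restore the caller's RNG state.
* The downshifted-normal imputation (`width` 0.3, `shift` 1.8, in sds of the
  matrix or column scope) uses plain normal draws; it is quarantined from
  `harmonize()` and exists solely so imputation-based strategies can be
  compared. Tail behavior of specific commercial implementations is not
  reproduced.
* Problem sizes in the test suite (up to 1500 features × 69 samples for the
  23-batch stress fixture, $10^5$ imputed cells for moment checks, 600
  features for recovery checks) were chosen as the smallest sizes at which
  the asserted statistical properties are stable.

## Known limitations

* Confounded designs (a covariate aliased with batch) are rejected, not
  resolved; no surrogate-variable machinery is included.
* Reference-batch anchoring of the empirical-Bayes corrector is not
  implemented; all batches shrink toward the pooled center.
* The nonparametric posterior is an exact $O(G^2)$ summation per batch;
  for sub-matrices of many thousands of features the parametric mode is the
  practical choice.
* `min_per_batch = 1` lets single values through to correction, where scale
  estimation is impossible; the neutral fallback (unit variance for that
  block) changes only location. Use the default unless you know why not.
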