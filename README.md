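# batchquilt

Batch-effect harmonization for incomplete feature-abundance matrices
(proteomics, metabolomics) **without imputation**.

## The problem

When several independently acquired omics runs are combined — different TMT
plexes, instruments, tissue-preservation protocols or acquisition dates —
each run (batch) carries systematic, non-biological location and scale
offsets, and every feature detected in one run but not another leaves whole
blocks of missing values. These blocks are *missing not at random*: a protein
absent from an entire batch is absent because of the experimental setting,
so imputing it distorts the batch-effect estimates. Yet the standard
correction tools (empirical-Bayes location/scale adjustment, linear-model
batch removal) reject matrices with missing cells, forcing users to either
discard most features or impute.

## The method

`batchquilt` resolves this with **missing-value-dependent matrix
dissection**:

1. For each feature, a batch counts as *present* when the feature has at
   least `min_per_batch` (default 2) observed values in it.
2. Features sharing the same set of present batches form a **sub-matrix**
   (the feature rows restricted to the columns of their present batches).
   Features present in fewer than two batches pass through untouched.
3. Each sub-matrix is corrected independently — they are complete *at the
   block level*, so batch parameters are estimable — and the corrected
   pieces are stitched back into the original layout. No cell is imputed,
   and scattered within-batch missing values are tolerated by available-case
   estimation throughout.

With *n* batches, at most

&nbsp;&nbsp;&nbsp;&nbsp; t<sub>n</sub> = Σ<sub>k=2..n</sub> C(n, k) = 2<sup>n</sup> − n − 1

correctable sub-matrices can arise (`max_submatrix_count()`); in practice the
number of features bounds it far lower. Sub-matrix corrections are
independent work units and run in parallel with bit-identical results for any
worker count.

Two correctors are provided, both authored here in available-case form:

* **Empirical Bayes (ComBat model)** — per feature *g* and batch *b*, the model
  y<sub>gb</sub> = α<sub>g</sub> + X β<sub>g</sub> + γ<sub>gb</sub> +
  δ<sub>gb</sub> ε, with γ shrunk toward a cross-feature normal prior and
  δ² toward an inverse-gamma prior (parametric mode, fixed-point posterior
  solution), or both shrunk by exact nonparametric likelihood weighting.
  Location-only adjustment via `mean_only = TRUE`. Matches `sva::ComBat` to
  numerical precision on complete data.
* **Linear model** — per-feature least squares with sum-to-zero batch
  contrasts; only the fitted batch component is subtracted. Matches
  `limma::removeBatchEffect` on complete data.

Around the core: preprocessing transforms (log2, column-median centering,
row-mean centering for SILAC-ratio emulation, internal reference scaling for
TMT plexes), a downshifted-normal imputation harness (comparison only; never
used by `harmonize()`), a ground-truth synthetic data generator, and
evaluation diagnostics (sample/feature CVs, vectorized Student t-tests,
between-batch variance fraction, missing-tolerant NIPALS PCA).

## Worked example

```r
library(batchquilt)

# four batches of six samples; batch shifts sd 1.5, noise scaling 0.7-1.4x,
# 30% of feature x batch blocks missing entirely, 5% scattered missingness
sim <- simulate_batches(n_features = 800, batch_sizes = c(6, 6, 6, 6), seed = 42)
mean(is.na(sim$matrix))
#> 0.328

h <- harmonize(sim$matrix, sim$design, algorithm = "eb", mode = "parametric")
h
#> Batch harmonization (eb/parametric)
#>   800 features x 24 samples, 4 batches
#>   corrected: 730 features in 11 pattern group(s); passthrough: 70

between_batch_variance_fraction(sim$matrix, sim$design)    # 0.535
between_batch_variance_fraction(h$corrected, sim$design)   # 0.031

ph <- sim$truth$phenotype
tt <- ttest_features(h$corrected,
                     colnames(sim$matrix)[ph == "case"],
                     colnames(sim$matrix)[ph == "ctrl"])
tt$n_significant
#> 114   (66 before harmonization; 80 features are truly differential)
```

The report says 730 of 800 features were correctable (present in ≥2
batches); they fell into 11 of the `max_submatrix_count(4) = 11` possible
presence patterns. Harmonization cut the fraction of variance attributable
to batch from 53.5% to 3.1% and raised the number of detected differential
features from 66 to 114 of 80 true positives plus false positives at
p < 0.05 — without imputing a single cell.

File-based workflows use `read_abundance()` (TSV: header of sample ids,
first column `ID`) and `read_design()` (CSV: `ID,sample,batch`), or the
shell interface:

```sh
Rscript inst/scripts/batchquilt harmonize \
  --data data.tsv --description design.csv \
  --algorithm eb --mode parametric --workers 4 \
  --output corrected.tsv --report report.json
```

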