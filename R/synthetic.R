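#' Simulate a multi-batch abundance matrix with known ground truth
#'
#' Generates log2-scale abundances emulating a multi-batch proteomic study:
#' per-feature baselines with within-group noise, a two-phenotype treatment
#' effect on a subset of features (identical in every batch), additive
#' per-batch location shifts `gamma_b`, multiplicative per-batch scaling
#' `delta_b` of the within-batch noise, whole (feature, batch) blocks blanked
#' at random (missing **not** at random — features absent from entire batches,
#' the hallmark of independently acquired runs), and scattered cells blanked
#' independently (missing at random). Fully reproducible under `seed`.
#'
#' Defaults mirror a hard but realistic integration scenario: four batches of
#' six samples, strong location effects (`gamma_sd = 1.5` log2 units), scale
#' effects between 0.7x and 1.4x, 30% of feature-batch blocks lost to MNAR
#' dropout and 5% of the remaining cells to MAR scatter.
#'
#' @param n_features Number of features.
#' @param batch_sizes Integer vector of samples per batch; at least two
#'   batches with at least two samples each.
#' @param phenotype Optional per-sample phenotype labels (2 levels used for
#'   the differential effect); default alternates two phenotypes within every
#'   batch so phenotype and batch are unconfounded.
#' @param de_fraction Fraction of features carrying the phenotype effect.
#' @param de_log2fc Log2 fold change added to phenotype level 2 on those
#'   features.
#' @param gamma_sd Standard deviation of the per-batch location shifts
#'   (log2 units).
#' @param delta_range Length-2 range from which per-batch noise scale factors
#'   are drawn uniformly.
#' @param mnar_prob Probability that a (feature, batch) block is entirely
#'   missing.
#' @param mar_rate Independent per-cell missingness rate applied after MNAR.
#' @param baseline_mean,baseline_sd Distribution of per-feature baseline
#'   abundances (log2 scale).
#' @param noise_sd Median within-batch replicate noise sd before batch
#'   scaling. Per-feature sds are drawn log-normally around it (see
#'   `noise_sd_spread`): replicate variability differs strongly between
#'   proteins in real data, and homogeneous feature variances are a
#'   degenerate corner case for empirical-Bayes priors.
#' @param noise_sd_spread Log-scale sd of the per-feature noise sds
#'   (0 = homogeneous variances).
#' @param censor_quantile Optional intensity-dependent (left-censoring)
#'   missingness: cells below this quantile of the complete matrix are
#'   additionally blanked. `NULL` (default) disables it.
#' @param seed Integer seed (required for reproducibility).
#' @return List: `matrix` (with MNAR/MAR applied), `design` (a
#'   `batch_design`), `truth` (list with `gamma`, `delta`, `de_features`,
#'   `de_log2fc`, `phenotype`, `dropout_mask` features x batches logical,
#'   `mar_rate`, `complete` — the matrix before any missingness).
#' @export
simulate_batches <- function(n_features = 1000L,
                             batch_sizes = c(6L, 6L, 6L, 6L),
                             phenotype = NULL,
                             de_fraction = 0.1, de_log2fc = 1,
                             gamma_sd = 1.5, delta_range = c(0.7, 1.4),
                             mnar_prob = 0.3, mar_rate = 0.05,
                             baseline_mean = 25, baseline_sd = 2,
                             noise_sd = 0.5, noise_sd_spread = 0.5,
                             censor_quantile = NULL,
                             seed = 1L) {
  stopifnot(n_features >= 1L, length(batch_sizes) >= 2L,
            all(batch_sizes >= 2L),
            de_fraction >= 0, de_fraction <= 1,
            gamma_sd >= 0, length(delta_range) == 2L,
            all(delta_range > 0), delta_range[1L] <= delta_range[2L],
            mnar_prob >= 0, mnar_prob < 1, mar_rate >= 0, mar_rate < 1,
            noise_sd > 0, noise_sd_spread >= 0)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)

  n_batches <- length(batch_sizes)
  n_samples <- sum(batch_sizes)
  batch <- factor(rep(sprintf("B%02d", seq_len(n_batches)), batch_sizes))
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  feature_ids <- sprintf("f%04d", seq_len(n_features))
  if (is.null(phenotype)) {
    phenotype <- unlist(lapply(batch_sizes, function(k)
      rep(c("ctrl", "case"), length.out = k)))
    pheno <- factor(phenotype, levels = c("ctrl", "case"))
  } else {
    pheno <- factor(phenotype)
  }
  stopifnot(length(phenotype) == n_samples)

  baseline <- stats::rnorm(n_features, baseline_mean, baseline_sd)
  gamma <- stats::rnorm(n_batches, 0, gamma_sd)
  delta <- stats::runif(n_batches, delta_range[1L], delta_range[2L])
  names(gamma) <- names(delta) <- levels(batch)

  n_de <- round(de_fraction * n_features)
  de_features <- if (n_de > 0) sort(sample(feature_ids, n_de)) else character(0)
  de_sign <- matrix(0, n_features, n_samples)
  if (n_de > 0 && nlevels(pheno) >= 2L)
    de_sign[match(de_features, feature_ids), pheno == levels(pheno)[2L]] <- 1

  feature_sd <- noise_sd * exp(stats::rnorm(n_features, 0, noise_sd_spread))
  eps <- matrix(stats::rnorm(n_features * n_samples),
                n_features, n_samples) * feature_sd
  jb <- as.integer(batch)
  complete <- baseline + de_sign * de_log2fc +
    matrix(gamma[jb], n_features, n_samples, byrow = TRUE) +
    sweep(eps, 2L, delta[jb], `*`)
  dimnames(complete) <- list(feature_ids, sample_ids)

  m <- complete
  dropout <- matrix(stats::runif(n_features * n_batches) < mnar_prob,
                    n_features, n_batches,
                    dimnames = list(feature_ids, levels(batch)))
  for (j in seq_len(n_batches))
    m[dropout[, j], jb == j] <- NA_real_
  if (mar_rate > 0) {
    mar <- matrix(stats::runif(n_features * n_samples) < mar_rate,
                  n_features, n_samples)
    m[mar] <- NA_real_
  }
  if (!is.null(censor_quantile)) {
    thr <- stats::quantile(complete, censor_quantile)
    m[!is.na(m) & m < thr] <- NA_real_
  }

  design <- as_batch_design(sample_ids, as.character(batch))
  truth <- list(gamma = gamma, delta = delta,
                de_features = de_features, de_log2fc = de_log2fc,
                phenotype = pheno,
                de_level = if (nlevels(pheno) >= 2L) levels(pheno)[2L]
                           else NA_character_,
                dropout_mask = dropout,
                feature_sd = feature_sd,
                mar_rate = mar_rate, complete = complete)
  list(matrix = m, design = design, truth = truth)
}
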