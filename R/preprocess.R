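#' @title Preprocessing transforms
#' @description
#' The dataset-preparation steps commonly applied before harmonization:
#' log2 transform, column-median centering, row-mean centering (spike-in
#' SILAC-ratio emulation), and internal reference scaling for isobaric-label
#' (TMT) plexes. All transforms preserve shape, ordering and (except for
#' imputation) the missing mask. The downshifted-normal imputation exists only
#' as a comparison harness for imputation-based strategies; [harmonize()]
#' never imputes.
#' @name preprocess
NULL

#' Log2-transform an abundance matrix
#'
#' Positive cells become `log2(value)`; non-positive cells become missing,
#' with a warning giving their count. Missing cells stay missing.
#'
#' @param x Numeric matrix.
#' @return Transformed matrix.
#' @export
log2_transform <- function(x) {
  bad <- !is.na(x) & x <= 0
  if (any(bad))
    warning(sum(bad), " non-positive cell(s) set to missing by log2 transform")
  x[bad] <- NA_real_
  log2(x)
}

#' Center each column on its median
#'
#' Subtracts each column's available-case median, so every column median
#' becomes 0 (the standard per-sample normalization for log-scale abundances).
#' All-missing columns are left unchanged with a warning.
#'
#' @param x Numeric matrix.
#' @return Centered matrix.
#' @export
median_center_columns <- function(x) {
  meds <- apply(x, 2L, stats::median, na.rm = TRUE)
  empty <- is.na(meds)
  if (any(empty)) {
    warning(sum(empty), " all-missing column(s) left unchanged")
    meds[empty] <- 0
  }
  sweep(x, 2L, meds)
}

#' Center each row (feature) on its mean
#'
#' Subtracts each feature's available-case mean, emulating spike-in SILAC
#' ratios (sample-to-reference log-ratios) for platforms without a labeled
#' reference. Row means become 0.
#'
#' @param x Numeric matrix.
#' @return Centered matrix.
#' @export
row_mean_center <- function(x) {
  means <- rowMeans(x, na.rm = TRUE)
  means[is.nan(means)] <- 0
  sweep(x, 1L, means)
}

#' Internal reference scaling (iRS) for multiplexed intensities
#'
#' For each feature and plex, divides all of that plex's raw reporter
#' intensities by the available-case arithmetic mean of the plex's reference
#' channels — the standard way to align isobaric-label multiplexes through a
#' common reference mix. Operates on raw (non-log) intensities; log-transform
#' afterwards. If all reference cells are missing for a (feature, plex), the
#' whole block becomes missing (counted in a warning).
#'
#' @param x Raw-intensity matrix (features x samples).
#' @param plex Plex (batch) label per column.
#' @param reference_samples Character vector of column names that are
#'   reference channels; every plex needs at least one.
#' @return Scaled matrix.
#' @export
irs_scale <- function(x, plex, reference_samples) {
  plex <- as.factor(plex)
  stopifnot(length(plex) == ncol(x))
  if (!all(reference_samples %in% colnames(x)))
    stop("unknown reference sample(s): ",
         paste(setdiff(reference_samples, colnames(x)), collapse = ", "))
  is_ref <- colnames(x) %in% reference_samples
  no_ref <- setdiff(levels(plex), unique(as.character(plex[is_ref])))
  if (length(no_ref))
    stop("plex(es) without a reference sample: ",
         paste(no_ref, collapse = ", "))
  out <- x
  n_blocks_lost <- 0L
  for (p in levels(plex)) {
    cols <- plex == p
    ref_mean <- rowMeans(x[, cols & is_ref, drop = FALSE], na.rm = TRUE)
    lost <- is.nan(ref_mean)
    n_blocks_lost <- n_blocks_lost + sum(lost)
    ref_mean[lost] <- NA_real_
    out[, cols] <- x[, cols, drop = FALSE] / ref_mean
  }
  if (n_blocks_lost)
    warning(n_blocks_lost,
            " (feature, plex) block(s) lost: all reference channels missing")
  out
}

#' Downshifted-normal imputation (comparison harness)
#'
#' Replaces missing cells with draws from
#' `Normal(m - shift * s, (width * s)^2)`, where `m` and `s` are the
#' available-case mean and standard deviation of the scope — the whole matrix
#' or the cell's column. This mimics the classic left-shifted imputation of
#' low-abundance missing values (defaults: width 0.3, downshift 1.8, in units
#' of the scope's standard deviation). It exists so imputation-based
#' strategies can be compared against harmonization; [harmonize()] itself
#' never calls it.
#'
#' @param x Numeric matrix.
#' @param width Standard deviation of the imputation distribution, as a
#'   fraction of the scope's sd (> 0).
#' @param shift Downshift of the imputation mean, in scope sds.
#' @param scope `"matrix"` (one distribution for all cells) or `"column"`.
#' @param seed Integer seed; the result is reproducible given the seed.
#' @return Matrix with no missing cells (except in scopes with < 2 observed
#'   values, which are left missing with a warning).
#' @export
impute_downshifted_normal <- function(x, width = 0.3, shift = 1.8,
                                      scope = c("matrix", "column"),
                                      seed = NULL) {
  scope <- match.arg(scope)
  stopifnot(width > 0)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  out <- x
  draw <- function(vals, idx_missing) {
    n_obs <- sum(!is.na(vals))
    if (n_obs < 2L) return(NULL)
    m <- mean(vals, na.rm = TRUE)
    s <- stats::sd(vals, na.rm = TRUE)
    stats::rnorm(length(idx_missing), mean = m - shift * s, sd = width * s)
  }
  if (scope == "matrix") {
    idx <- which(is.na(x))
    if (length(idx)) {
      d <- draw(as.vector(x), idx)
      if (is.null(d)) warning("matrix has < 2 observed values; nothing imputed")
      else out[idx] <- d
    }
  } else {
    skipped <- 0L
    for (j in seq_len(ncol(x))) {
      idx <- which(is.na(x[, j]))
      if (!length(idx)) next
      d <- draw(x[, j], idx)
      if (is.null(d)) skipped <- skipped + 1L else out[idx, j] <- d
    }
    if (skipped)
      warning(skipped, " column(s) with < 2 observed values left unimputed")
  }
  out
}
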