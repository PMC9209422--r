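#' @title Harmonization diagnostics
#' @description
#' The statistics used to judge whether batch structure was removed while
#' biological structure survived: per-sample means and coefficients of
#' variation, per-feature CVs (overall and per batch), vectorized two-sample
#' pooled-variance t-tests with significance counts, the between-batch
#' variance fraction, and a missing-value-tolerant NIPALS PCA.
#'
#' CVs are computed on whatever scale the matrix is in; on log scale, means
#' near zero make the CV unstable, so interpret log-scale CVs with care (or
#' compute them on back-transformed intensities).
#' @name evaluation
NULL

cv_pct <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) < 2L) return(NA_real_)
  m <- mean(v)
  if (m == 0) return(NA_real_)
  100 * stats::sd(v) / m
}

#' Per-sample mean and coefficient of variation
#'
#' @param x Numeric matrix (features x samples).
#' @return data.frame with `sample`, `mean`, `cv` (percent; `NA` when the
#'   column mean is 0 or fewer than 2 values are observed).
#' @export
sample_stats <- function(x) {
  data.frame(sample = colnames(x),
             mean = colMeans(x, na.rm = TRUE),
             cv = apply(x, 2L, cv_pct),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overall and per-batch coefficient of variation of one feature
#'
#' @param x Numeric matrix.
#' @param design A `batch_design`.
#' @param feature_id Row name of the feature.
#' @return List with `overall` (CV%) and `per_batch` (named vector, `NA` for
#'   batches with < 2 observed values).
#' @export
feature_cv <- function(x, design, feature_id) {
  if (!feature_id %in% rownames(x))
    stop("unknown feature: ", feature_id)
  v <- x[feature_id, ]
  b <- batch_factor(x, design)
  list(overall = cv_pct(v),
       per_batch = vapply(levels(b), function(lv) cv_pct(v[b == lv]),
                          numeric(1L)))
}

#' Two-sample pooled-variance t-test per feature
#'
#' Classic Student's (equal-variance) two-sided t-test of group A vs group B,
#' vectorized over features on available cases. Features with fewer than two
#' observed values in either group are excluded and counted. Welch's
#' unequal-variance test is available via `var_equal = FALSE`.
#'
#' @param x Numeric matrix.
#' @param group_a,group_b Character vectors of column names.
#' @param alpha Significance level (default 0.05).
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return List with `table` (data.frame: feature, t, df, p, significant),
#'   `n_significant`, `n_excluded`.
#' @export
ttest_features <- function(x, group_a, group_b, alpha = 0.05,
                           var_equal = TRUE) {
  stopifnot(all(group_a %in% colnames(x)), all(group_b %in% colnames(x)))
  xa <- x[, group_a, drop = FALSE]; xb <- x[, group_b, drop = FALSE]
  na_ <- rowSums(!is.na(xa)); nb_ <- rowSums(!is.na(xb))
  ok <- na_ >= 2L & nb_ >= 2L
  ma <- rowMeans(xa, na.rm = TRUE); mb <- rowMeans(xb, na.rm = TRUE)
  va <- rowSums((xa - ma)^2, na.rm = TRUE) / pmax(na_ - 1L, 1L)
  vb <- rowSums((xb - mb)^2, na.rm = TRUE) / pmax(nb_ - 1L, 1L)
  if (var_equal) {
    sp2 <- ((na_ - 1L) * va + (nb_ - 1L) * vb) / (na_ + nb_ - 2L)
    se <- sqrt(sp2 * (1 / na_ + 1 / nb_))
    df <- na_ + nb_ - 2L
  } else {
    se <- sqrt(va / na_ + vb / nb_)
    df <- (va / na_ + vb / nb_)^2 /
      ((va / na_)^2 / (na_ - 1L) + (vb / nb_)^2 / (nb_ - 1L))
  }
  t_stat <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  t_stat[!ok] <- NA_real_; p[!ok] <- NA_real_; df[!ok] <- NA_real_
  tab <- data.frame(feature = rownames(x), t = t_stat, df = df, p = p,
                    significant = !is.na(p) & p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       n_significant = sum(tab$significant),
       n_excluded = sum(!ok))
}

#' Fraction of variance attributable to batch
#'
#' Per feature, the one-way between-batch sum of squares over the total sum
#' of squares (available-case; batches with < 2 observed values for the
#' feature are dropped from its decomposition), averaged over features with
#' at least two batches present. Under no batch effect this approaches the
#' null expectation `(b - 1) / (N - 1)`; injected batch shifts push it toward
#' 1, and successful harmonization pushes it back down.
#'
#' @param x Numeric matrix.
#' @param design A `batch_design`.
#' @param min_per_batch Presence threshold per batch (default 2).
#' @return Scalar in `[0, 1]` (`NA` if no feature qualifies).
#' @export
between_batch_variance_fraction <- function(x, design, min_per_batch = 2L) {
  b <- batch_factor(x, design)
  if (nlevels(b) < 2L) stop("need >= 2 batches")
  fracs <- apply(x, 1L, function(v) {
    keep <- !is.na(v)
    bb <- droplevels(b[keep]); vv <- v[keep]
    sizes <- table(bb)
    use <- names(sizes)[sizes >= min_per_batch]
    if (length(use) < 2L) return(NA_real_)
    sel <- bb %in% use
    vv <- vv[sel]; bb <- droplevels(bb[sel])
    grand <- mean(vv)
    means <- tapply(vv, bb, mean)
    ssb <- sum(table(bb) * (means - grand)^2)
    sst <- sum((vv - grand)^2)
    if (sst == 0) return(NA_real_)
    ssb / sst
  })
  mean(fracs, na.rm = TRUE)
}

#' Missing-value-tolerant NIPALS principal component analysis
#'
#' Nonlinear iterative partial least squares PCA on a features x samples
#' matrix: samples are the observations; each feature is centered on its
#' available-case mean; missing cells are simply skipped in the alternating
#' score/loading regressions, and the rank-1 component is deflated before the
#' next one is extracted. The sign of each component is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x Numeric matrix (features x samples).
#' @param n_components Number of components (>= 1).
#' @param max_iter Maximum iterations per component (default 500).
#' @param tol Relative convergence tolerance on the score vector
#'   (default 1e-9). Non-convergence yields a warning and the last iterate.
#' @return List: `scores` (samples x components), `loadings`
#'   (features x components, unit norm), `explained_variance` (fraction of the
#'   total available-case variance captured by each component).
#' @export
nipals_pca <- function(x, n_components = 2L, max_iter = 500L, tol = 1e-9) {
  stopifnot(n_components >= 1L)
  # samples as rows; center each variable (feature) on its available mean
  E <- t(x - rowMeans(x, na.rm = TRUE))
  n <- nrow(E); p <- ncol(E)
  total_ss <- sum(E^2, na.rm = TRUE)
  obs <- !is.na(E)
  E0 <- E; E0[!obs] <- 0

  scores <- matrix(NA_real_, n, n_components,
                   dimnames = list(rownames(E),
                                   paste0("PC", seq_len(n_components))))
  loadings <- matrix(NA_real_, p, n_components,
                     dimnames = list(colnames(E),
                                     paste0("PC", seq_len(n_components))))
  ev <- numeric(n_components)

  for (h in seq_len(n_components)) {
    j0 <- which.max(colSums(E0^2))
    t_vec <- E0[, j0]
    if (all(t_vec == 0)) t_vec <- stats::rnorm(n)  # degenerate start
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # p_k = sum_i t_i E_ik / sum_i t_i^2  over observed cells
      pv <- colSums(E0 * t_vec) / colSums(obs * t_vec^2)
      pv[!is.finite(pv)] <- 0
      pv <- pv / sqrt(sum(pv^2))
      t_new <- rowSums(sweep(E0, 2L, pv, `*`)) /
        rowSums(sweep(obs, 2L, pv^2, `*`))
      t_new[!is.finite(t_new)] <- 0
      if (sqrt(sum((t_new - t_vec)^2)) <=
          tol * max(sqrt(sum(t_new^2)), 1e-300)) {
        t_vec <- t_new; converged <- TRUE; break
      }
      t_vec <- t_new
    }
    if (!converged)
      warning("NIPALS component ", h, " did not converge in ", max_iter,
              " iterations; using last iterate")
    pv <- colSums(E0 * t_vec) / colSums(obs * t_vec^2)
    pv[!is.finite(pv)] <- 0
    nrm <- sqrt(sum(pv^2))
    if (nrm > 0) pv <- pv / nrm
    if (pv[which.max(abs(pv))] < 0) { pv <- -pv; t_vec <- -t_vec }
    scores[, h] <- t_vec
    loadings[, h] <- pv
    ev[h] <- sum((outer(t_vec, pv)[obs])^2) / total_ss
    # deflate on observed cells only
    E0 <- E0 - outer(t_vec, pv)
    E0[!obs] <- 0
  }
  list(scores = scores, loadings = loadings, explained_variance = ev)
}
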