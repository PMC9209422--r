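#' @title Available-case empirical-Bayes (ComBat-style) batch correction
#' @description
#' Location/scale batch adjustment in the classic empirical-Bayes framework:
#' per feature, batch location effects (gamma) and batch scale effects
#' (delta^2) are estimated on standardized data and shrunk toward cross-feature
#' priors (normal for gamma, inverse-gamma for delta^2) before removal.
#' Unlike the reference implementations, every moment here is computed on
#' available cases only, so sub-matrices with scattered missing values are
#' corrected without imputation; the caller must guarantee at least
#' two observed values per (feature, batch) block.
#' @name correction_eb
NULL

VAR_FLOOR <- 1e-8

# covariate model matrix (no intercept column), aligned to sample order
covariate_matrix <- function(covariates, sample_ids) {
  if (is.null(covariates)) return(NULL)
  if (is.vector(covariates) || is.factor(covariates))
    covariates <- data.frame(covariate = covariates)
  if (is.matrix(covariates)) covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(sample_ids))
    stop("covariates must have one row per sample (", length(sample_ids), ")")
  if (!is.null(rownames(covariates)) &&
      all(sample_ids %in% rownames(covariates)))
    covariates <- covariates[sample_ids, , drop = FALSE]
  mm <- stats::model.matrix(~ ., data = covariates)
  mm[, -1L, drop = FALSE]
}

#' Standardize a sub-matrix for empirical-Bayes fitting
#'
#' Per feature, batch means (and optional covariate effects) are fit by
#' available-case least squares; the grand mean `alpha_g` is the
#' available-count-weighted mean of the batch means, and the pooled variance
#' `sigma2_g` is the mean squared residual over the feature's observed cells
#' (divisor = number of observed cells). Standardized values are
#' `z = (y - alpha_g - covariate fit) / sqrt(sigma2_g)`.
#'
#' @param x Numeric sub-matrix (features x samples, `NA` = missing); every
#'   (feature, batch) block needs >= 2 observed values.
#' @param batch Factor of batch labels aligned to `colnames(x)`; >= 2 levels.
#' @param covariates Optional per-sample covariates (vector, factor,
#'   data.frame or matrix) whose effects are preserved through correction.
#' @return List: `z` (standardized matrix), `alpha` (per-feature grand mean),
#'   `sigma2` (per-feature pooled variance, floored at 1e-8), `stand_mean`
#'   (features x samples matrix of alpha + covariate fit, subtracted before
#'   scaling and re-added by [combat_adjust()]), `counts` (features x batches
#'   observed-value counts), `batch` (the factor, unused levels dropped).
#' @export
eb_standardize <- function(x, batch, covariates = NULL) {
  batch <- droplevels(as.factor(batch))
  stopifnot(is.matrix(x), length(batch) == ncol(x))
  if (nlevels(batch) < 2L) stop("need >= 2 batches")
  G <- nrow(x)
  lv <- levels(batch)
  obs <- !is.na(x)
  counts <- vapply(lv, function(b)
    rowSums(obs[, batch == b, drop = FALSE]), numeric(G))
  if (G == 1L) counts <- matrix(counts, nrow = 1L)
  dimnames(counts) <- list(rownames(x), lv)
  if (any(counts < 2L))
    stop("every (feature, batch) block needs >= 2 observed values; ",
         "violated for feature(s): ",
         paste(utils::head(rownames(x)[rowSums(counts < 2L) > 0], 5L),
               collapse = ", "))

  cm <- covariate_matrix(covariates, colnames(x))
  if (is.null(cm)) {
    bmeans <- vapply(lv, function(b)
      rowMeans(x[, batch == b, drop = FALSE], na.rm = TRUE), numeric(G))
    if (G == 1L) bmeans <- matrix(bmeans, nrow = 1L)
    n_tot <- rowSums(counts)
    alpha <- rowSums(bmeans * counts) / n_tot
    fitted <- bmeans[, as.integer(batch), drop = FALSE]
    resid <- x - fitted
    sigma2 <- rowSums(resid^2, na.rm = TRUE) / n_tot
    cov_fit <- matrix(0, G, ncol(x))
  } else {
    B <- stats::model.matrix(~ 0 + batch)
    X <- cbind(B, cm)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
      stop("batch and covariates are confounded (rank-deficient design); ",
           "aliased column(s): ", paste(aliased, collapse = ", "))
    }
    alpha <- numeric(G); sigma2 <- numeric(G)
    cov_fit <- matrix(0, G, ncol(x))
    fitted <- matrix(NA_real_, G, ncol(x))
    for (g in seq_len(G)) {
      ok <- obs[g, ]
      fit <- stats::lm.fit(X[ok, , drop = FALSE], x[g, ok])
      if (anyNA(fit$coefficients))
        stop("rank-deficient available-case design for feature ",
             rownames(x)[g])
      beta <- fit$coefficients
      bcoef <- beta[seq_along(lv)]
      alpha[g] <- sum(counts[g, ] * bcoef) / sum(counts[g, ])
      cov_fit[g, ] <- as.vector(cm %*% beta[-seq_along(lv)])
      fitted[g, ] <- as.vector(X %*% beta)
      sigma2[g] <- sum((x[g, ok] - fitted[g, ok])^2) / sum(ok)
    }
  }
  floored <- sigma2 < VAR_FLOOR
  if (any(floored)) {
    warning(sum(floored), " feature(s) with (near-)constant values: ",
            "pooled variance floored at ", VAR_FLOOR)
    sigma2[floored] <- VAR_FLOOR
  }
  stand_mean <- alpha + cov_fit
  z <- (x - stand_mean) / sqrt(sigma2)
  if (any(floored)) {   # constant features standardize to exactly 0
    zf <- z[floored, , drop = FALSE]
    zf[!is.na(zf)] <- 0
    z[floored, ] <- zf
  }
  list(z = z, alpha = alpha, sigma2 = sigma2, stand_mean = stand_mean,
       counts = counts, batch = batch)
}

#' Fit empirical-Bayes posteriors for batch effects
#'
#' From standardized data, per-batch location estimates
#' `gamma_hat[g,b]` (available-case mean) and scale estimates
#' `delta2_hat[g,b]` (available-case sample variance, divisor n-1) are shrunk
#' across features. Parametric mode places a normal prior on gamma
#' (moments = cross-feature mean/variance of `gamma_hat`) and an inverse-gamma
#' prior on delta^2 (method-of-moments), solving the coupled posterior
#' equations by fixed-point iteration (tolerance 1e-4, max 500 iterations).
#' Non-parametric mode computes, for each feature, the likelihood-weighted
#' average of the other features' `(gamma_hat, delta2_hat)` under the normal
#' likelihood of the feature's standardized batch values — an exact,
#' deterministic summation (weights in log space for stability).
#'
#' @param std Result of [eb_standardize()].
#' @param mode `"parametric"` or `"nonparametric"`.
#' @param mean_only If `TRUE`, only location is adjusted: `delta2_star` is
#'   fixed at 1.
#' @return List of matrices (features x batches): `gamma_hat`, `delta2_hat`,
#'   `gamma_star`, `delta2_star`; plus per-batch prior moments `gamma_bar`,
#'   `tau2`, `lambda`, `theta` (parametric mode; `NA` otherwise).
#' @export
eb_fit_posteriors <- function(std, mode = c("parametric", "nonparametric"),
                              mean_only = FALSE) {
  mode <- match.arg(mode)
  z <- std$z; batch <- std$batch; counts <- std$counts
  lv <- levels(batch); G <- nrow(z); nb <- length(lv)

  gamma_hat <- matrix(NA_real_, G, nb, dimnames = list(rownames(z), lv))
  delta2_hat <- gamma_hat
  for (j in seq_len(nb)) {
    zb <- z[, batch == lv[j], drop = FALSE]
    gamma_hat[, j] <- rowMeans(zb, na.rm = TRUE)
    n <- counts[, j]
    delta2_hat[, j] <- rowSums((zb - gamma_hat[, j])^2, na.rm = TRUE) /
      pmax(n - 1, 1)
    delta2_hat[n < 2, j] <- 1   # no variance estimate: neutral scale
  }
  delta2_hat <- pmax(delta2_hat, VAR_FLOOR)

  gamma_bar <- rep(NA_real_, nb); tau2 <- rep(NA_real_, nb)
  lambda <- rep(NA_real_, nb); theta <- rep(NA_real_, nb)
  names(gamma_bar) <- names(tau2) <- names(lambda) <- names(theta) <- lv

  if (G < 2L) {
    warning("single-feature sub-matrix: no cross-feature shrinkage possible; ",
            "using unshrunken estimates")
    delta2_star <- if (mean_only) array(1, dim(delta2_hat),
                                        dimnames(delta2_hat)) else delta2_hat
    return(list(gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                gamma_star = gamma_hat, delta2_star = delta2_star,
                gamma_bar = gamma_bar, tau2 = tau2,
                lambda = lambda, theta = theta))
  }

  gamma_star <- gamma_hat; delta2_star <- delta2_hat
  if (mode == "parametric") {
    for (j in seq_len(nb)) {
      gh <- gamma_hat[, j]; dh <- delta2_hat[, j]; n <- counts[, j]
      gamma_bar[j] <- mean(gh); tau2[j] <- stats::var(gh)
      m <- mean(dh); v <- stats::var(dh)
      scale_prior <- !mean_only && v > 0
      if (scale_prior) {
        lambda[j] <- m^2 / v + 2
        theta[j] <- m^3 / v + m
      }
      if (mean_only) {
        gamma_star[, j] <- if (tau2[j] > 0)
          (n * tau2[j] * gh + gamma_bar[j]) / (n * tau2[j] + 1) else gh
        delta2_star[, j] <- 1
      } else if (!scale_prior) {
        # degenerate scale prior: shrink location only, keep raw variances
        gamma_star[, j] <- if (tau2[j] > 0)
          (n * tau2[j] * gh + dh * gamma_bar[j]) / (n * tau2[j] + dh) else gh
        delta2_star[, j] <- dh
      } else {
        zb <- z[, batch == lv[j], drop = FALSE]
        g_old <- gh; d_old <- dh
        converged <- FALSE
        for (it in seq_len(500L)) {
          g_new <- if (tau2[j] > 0)
            (n * tau2[j] * gh + d_old * gamma_bar[j]) /
              (n * tau2[j] + d_old) else gh
          sum2 <- rowSums((zb - g_new)^2, na.rm = TRUE)
          d_new <- (theta[j] + 0.5 * sum2) / (n / 2 + lambda[j] - 1)
          change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                        abs(d_new - d_old) / d_old)
          g_old <- g_new; d_old <- d_new
          if (change <= 1e-4) { converged <- TRUE; break }
        }
        if (!converged)
          warning("EB fixed point did not converge for batch '", lv[j],
                  "'; using last iterate")
        gamma_star[, j] <- g_old
        delta2_star[, j] <- pmax(d_old, VAR_FLOOR)
      }
    }
  } else {
    for (j in seq_len(nb)) {
      zb <- z[, batch == lv[j], drop = FALSE]
      gh <- gamma_hat[, j]; dh <- delta2_hat[, j]
      s1 <- rowSums(zb, na.rm = TRUE)
      s2 <- rowSums(zb^2, na.rm = TRUE)
      n <- counts[, j]
      for (g in seq_len(G)) {
        # log-likelihood of feature g's batch values under every other
        # feature's (gamma_hat, delta2_hat)
        ll <- -0.5 * n[g] * log(2 * pi * dh) -
          (s2[g] - 2 * gh * s1[g] + n[g] * gh^2) / (2 * dh)
        ll[g] <- -Inf
        w <- exp(ll - max(ll[-g]))
        w[g] <- 0
        sw <- sum(w)
        gamma_star[g, j] <- sum(w * gh) / sw
        delta2_star[g, j] <- sum(w * dh) / sw
      }
    }
    if (mean_only) delta2_star[] <- 1
    delta2_star <- pmax(delta2_star, VAR_FLOOR)
  }

  list(gamma_hat = gamma_hat, delta2_hat = delta2_hat,
       gamma_star = gamma_star, delta2_star = delta2_star,
       gamma_bar = gamma_bar, tau2 = tau2, lambda = lambda, theta = theta)
}

#' Empirical-Bayes batch adjustment of one sub-matrix
#'
#' Runs [eb_standardize()] and [eb_fit_posteriors()], then removes the
#' shrunken batch effects:
#' `y* = sqrt(sigma2_g) * (z - gamma_star) / sqrt(delta2_star) + alpha_g +
#' covariate fit`, with the posterior adjustments taken at the cell's batch.
#' Missing cells stay missing; shape and ordering are untouched.
#'
#' @inheritParams eb_standardize
#' @inheritParams eb_fit_posteriors
#' @param return_params Also return the fitted [eb_fit_posteriors()] object.
#' @return Corrected matrix, or (with `return_params`) a list
#'   `list(corrected, params)`.
#' @examples
#' x <- matrix(c(1, 2, 3, 4), 1, 4,
#'             dimnames = list("p1", paste0("s", 1:4)))
#' b <- factor(c("A", "A", "B", "B"))
#' suppressWarnings(combat_adjust(x, b, mean_only = TRUE))  # batch means 2.5
#' @export
combat_adjust <- function(x, batch, mode = c("parametric", "nonparametric"),
                          mean_only = FALSE, covariates = NULL,
                          return_params = FALSE) {
  mode <- match.arg(mode)
  std <- eb_standardize(x, batch, covariates)
  post <- eb_fit_posteriors(std, mode, mean_only)
  jb <- as.integer(std$batch)
  gs <- post$gamma_star[, jb, drop = FALSE]
  ds <- post$delta2_star[, jb, drop = FALSE]
  corrected <- sqrt(std$sigma2) * (std$z - gs) / sqrt(ds) + std$stand_mean
  dimnames(corrected) <- dimnames(x)
  if (return_params) list(corrected = corrected, params = post) else corrected
}
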