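# Shared fixtures, all built in code.

# named matrix constructor
mk_matrix <- function(values, feature_ids, sample_ids) {
  matrix(values, nrow = length(feature_ids), byrow = TRUE,
         dimnames = list(feature_ids, sample_ids))
}

# single feature, two batches of two: the hand-computed oracle case
single_feature_fixture <- function() {
  list(x = mk_matrix(c(1, 2, 3, 4), "p1", paste0("s", 1:4)),
       batch = factor(c("A", "A", "B", "B")))
}

# 4 features x 3 batches (2 samples each): f1 in all batches, f2/f4 in {A,B},
# f3 in {A} only
toy_dissection_fixture <- function() {
  sample_ids <- paste0("s", 1:6)
  x <- mk_matrix(rep(10, 24), paste0("f", 1:4), sample_ids)
  x["f2", 5:6] <- NA   # f2 misses batch C
  x["f4", 5:6] <- NA   # f4 misses batch C
  x["f3", 3:6] <- NA   # f3 only in batch A
  x[1, ] <- c(1, 2, 3, 4, 5, 6)
  x["f2", 1:4] <- c(2, 4, 6, 8)
  x["f4", 1:4] <- c(1, 3, 5, 7)
  x["f3", 1:2] <- c(9, 11)
  design <- as_batch_design(sample_ids, rep(c("A", "B", "C"), each = 2))
  list(x = x, design = design)
}

# random matrix with controlled missingness
random_na_matrix <- function(n_features, n_samples, na_frac, seed) {
  set.seed(seed)
  x <- matrix(rnorm(n_features * n_samples, 20, 2), n_features, n_samples,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              sprintf("s%03d", seq_len(n_samples))))
  x[sample(length(x), round(na_frac * length(x)))] <- NA_real_
  x
}

# independent brute-force oracle for the non-parametric EB posteriors:
# direct density products, plain summation, no log-space tricks
np_posterior_bruteforce <- function(z, batch, counts) {
  lv <- levels(batch)
  G <- nrow(z)
  gamma_hat <- sapply(lv, function(b) rowMeans(z[, batch == b, drop = FALSE],
                                               na.rm = TRUE))
  delta2_hat <- sapply(lv, function(b) {
    zb <- z[, batch == b, drop = FALSE]
    apply(zb, 1L, function(v) stats::var(v[!is.na(v)]))
  })
  if (G == 1L) {
    gamma_hat <- matrix(gamma_hat, 1L); delta2_hat <- matrix(delta2_hat, 1L)
  }
  gamma_star <- gamma_hat; delta2_star <- delta2_hat
  for (j in seq_along(lv)) {
    zb <- z[, batch == lv[j], drop = FALSE]
    for (g in seq_len(G)) {
      vals <- zb[g, !is.na(zb[g, ])]
      w <- numeric(G)
      for (gp in seq_len(G)) {
        if (gp == g) next
        w[gp] <- prod(stats::dnorm(vals, gamma_hat[gp, j],
                                   sqrt(delta2_hat[gp, j])))
      }
      gamma_star[g, j] <- sum(w * gamma_hat[, j]) / sum(w)
      delta2_star[g, j] <- sum(w * delta2_hat[, j]) / sum(w)
    }
  }
  list(gamma_star = gamma_star, delta2_star = delta2_star)
}

# independent oracle for the parametric fixed point, one batch at a time
param_fixedpoint_bruteforce <- function(zb, gh, dh, n, gbar, t2, lambda,
                                        theta, tol = 1e-4) {
  g_old <- gh; d_old <- dh
  repeat {
    g_new <- (n * t2 * gh + d_old * gbar) / (n * t2 + d_old)
    sum2 <- rowSums((zb - g_new)^2, na.rm = TRUE)
    d_new <- (theta + 0.5 * sum2) / (n / 2 + lambda - 1)
    if (max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
            abs(d_new - d_old) / d_old) <= tol) break
    g_old <- g_new; d_old <- d_new
  }
  list(gamma_star = g_new, delta2_star = d_new)
}
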