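test_that("per-sample statistics handle edge cases", {
  x <- mk_matrix(c(2, 10, -1,
                   4, 10, 1), c("f1", "f2"), c("s1", "s2", "s3"))
  st <- sample_stats(x)
  expect_equal(st$mean, c(3, 10, 0))
  expect_equal(st$cv[1], 100 * sqrt(2) / 3, tolerance = 1e-12)  # 47.14%
  expect_equal(st$cv[2], 0)
  expect_true(is.na(st$cv[3]))  # mean 0: CV undefined
})

test_that("feature CVs are available-case, overall and per batch", {
  d <- as_batch_design(paste0("s", 1:4), c("A", "A", "B", "B"))
  x <- mk_matrix(c(10, 10, 10, 10,
                   9, 11, 19, 21), c("f1", "f2"), paste0("s", 1:4))
  cv1 <- feature_cv(x, d, "f1")
  expect_equal(cv1$overall, 0)
  expect_equal(unname(cv1$per_batch), c(0, 0))

  cv2 <- feature_cv(x, d, "f2")
  expect_equal(unname(cv2$per_batch),
               c(100 * sd(c(9, 11)) / 10, 100 * sd(c(19, 21)) / 20),
               tolerance = 1e-12)          # 14.14% and 7.07%
  expect_equal(cv2$overall, 100 * sd(c(9, 11, 19, 21)) / 15,
               tolerance = 1e-12)          # 39.25%

  x[2, 3] <- NA  # batch B down to 1 value for f2
  expect_true(is.na(feature_cv(x, d, "f2")$per_batch[["B"]]))
  expect_error(feature_cv(x, d, "nope"), "unknown feature")
})

test_that("correcting an injected shift cannot raise a null feature's overall CV", {
  sim <- simulate_batches(n_features = 150, batch_sizes = c(6, 6),
                          de_fraction = 0, gamma_sd = 2,
                          delta_range = c(1, 1), mnar_prob = 0,
                          mar_rate = 0, seed = 14)
  h <- harmonize(sim$matrix, sim$design, algorithm = "linear")
  pre <- apply(sim$matrix, 1, function(v) sd(v) / mean(v))
  post <- apply(h$corrected, 1, function(v) sd(v) / mean(v))
  expect_true(all(post <= pre + 1e-12))
})

test_that("pooled t-tests match the textbook formula and the reference library", {
  x <- mk_matrix(c(1, 2, 3, 4, 5, 6,
                   1, 2, 3, 1, 2, 3,
                   1, 2, 3, 4, NA, NA), paste0("f", 1:3), paste0("s", 1:6))
  tt <- ttest_features(x, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(abs(tt$table$t[1]), 3.674, tolerance = 1e-3)
  expect_equal(tt$table$df[1], 4)
  expect_equal(tt$table$p[1], 0.0214, tolerance = 1e-2)
  expect_true(tt$table$significant[1])
  expect_equal(tt$table$t[2], 0)
  expect_equal(tt$table$p[2], 1)
  expect_false(tt$table$significant[2])
  expect_true(is.na(tt$table$p[3]))   # one group has a single value
  expect_identical(tt$n_excluded, 1L)
  expect_identical(tt$n_significant, 1L)

  # agreement with stats::t.test to 1e-10 on complete data
  set.seed(15)
  y <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(paste0("f", 1:30), paste0("s", 1:8)))
  ty <- ttest_features(y, paste0("s", 1:4), paste0("s", 5:8))
  for (g in c(1, 7, 30)) {
    ref <- t.test(y[g, 1:4], y[g, 5:8], var.equal = TRUE)
    expect_equal(ty$table$t[g], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ty$table$p[g], ref$p.value, tolerance = 1e-10)
  }
  # Welch option agrees with the reference too
  tw <- ttest_features(y, paste0("s", 1:4), paste0("s", 5:8),
                       var_equal = FALSE)
  refw <- t.test(y[1, 1:4], y[1, 5:8])
  expect_equal(tw$table$t[1], unname(refw$statistic), tolerance = 1e-10)
  expect_equal(tw$table$p[1], refw$p.value, tolerance = 1e-10)
})

test_that("between-batch variance fraction behaves at its extremes and under the null", {
  d <- as_batch_design(paste0("s", 1:4), c("A", "A", "B", "B"))
  x <- mk_matrix(c(1, 1, 5, 5), "f1", paste0("s", 1:4))
  expect_equal(between_batch_variance_fraction(x, d), 1)

  # null expectation (b - 1) / (N - 1)
  set.seed(16)
  n <- 30
  xn <- matrix(rnorm(2000 * n), 2000, n,
               dimnames = list(paste0("f", 1:2000), paste0("s", 1:n)))
  dn <- as_batch_design(colnames(xn), rep(c("A", "B", "C"), each = 10))
  expect_equal(between_batch_variance_fraction(xn, dn), 2 / (n - 1),
               tolerance = 0.05)
})

test_that("statistics are invariant to a joint column permutation", {
  sim <- simulate_batches(n_features = 80, batch_sizes = c(4, 4, 4),
                          mnar_prob = 0.2, mar_rate = 0.05, seed = 19)
  set.seed(20)
  perm <- sample(ncol(sim$matrix))
  xp <- sim$matrix[, perm]
  expect_equal(between_batch_variance_fraction(sim$matrix, sim$design),
               between_batch_variance_fraction(xp, sim$design),
               tolerance = 1e-12)
  expect_equal(feature_cv(sim$matrix, sim$design, "f0001"),
               feature_cv(xp, sim$design, "f0001"), tolerance = 1e-12)
})

test_that("NIPALS matches classical PCA on complete data up to sign", {
  set.seed(25)
  x <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:12)))
  np <- nipals_pca(x, n_components = 4)
  ref <- prcomp(t(x), center = TRUE)
  for (k in 1:4) {
    expect_equal(unname(abs(np$scores[, k])), abs(unname(ref$x[, k])),
                 tolerance = 1e-6)
    # sign convention: largest-magnitude loading positive
    expect_gt(np$loadings[which.max(abs(np$loadings[, k])), k], 0)
  }
  expect_equal(np$explained_variance,
               (ref$sdev^2 / sum(ref$sdev^2))[1:4], tolerance = 1e-6)
  expect_true(all(diff(np$explained_variance) <= 1e-8))
})

test_that("NIPALS recovers a rank-1 structure despite punched-out cells", {
  set.seed(26)
  t_true <- rnorm(15); p_true <- rnorm(60)
  x <- outer(p_true, t_true)
  dimnames(x) <- list(paste0("f", 1:60), paste0("s", 1:15))
  x[sample(length(x), round(0.1 * length(x)))] <- NA
  np <- nipals_pca(x, n_components = 2)
  expect_gt(np$explained_variance[1], 0.99)
})
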