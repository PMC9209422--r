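test_that("standardization matches hand least squares, handles missing and constant rows", {
  fx <- single_feature_fixture()
  std <- eb_standardize(fx$x, fx$batch)
  # batch means 1.5 / 3.5, counts 2/2 -> alpha 2.5; residuals +-0.5, 1/N divisor
  expect_equal(unname(std$alpha), 2.5)
  expect_equal(unname(std$sigma2), 0.25)
  expect_equal(unname(std$z["p1", ]), c(-3, -1, 1, 3))

  # constant feature: variance floored, standardized values exactly 0
  xc <- mk_matrix(rep(7, 4), "p1", paste0("s", 1:4))
  expect_warning(stdc <- eb_standardize(xc, fx$batch), "floored")
  expect_identical(unname(stdc$z["p1", ]), rep(0, 4))

  # missing cell: moments recomputed on available cases
  x3 <- mk_matrix(c(1, 2, 6, 3, 4, NA), "p1", paste0("s", 1:6))
  b3 <- factor(c("A", "A", "A", "B", "B", "B"))
  std3 <- eb_standardize(x3, b3)
  # batch A mean 3 (3 values), batch B mean 3.5 (2 values)
  expect_equal(unname(std3$alpha), (3 * 3 + 2 * 3.5) / 5)
  resid <- c(1 - 3, 2 - 3, 6 - 3, 3 - 3.5, 4 - 3.5)
  expect_equal(unname(std3$sigma2), mean(resid^2))
  expect_identical(is.na(std3$z), is.na(x3))

  # too few values per block is rejected
  expect_error(eb_standardize(mk_matrix(c(1, 2, 3, NA), "p1", paste0("s", 1:4)),
                              fx$batch), ">= 2 observed")
})

test_that("standardization rejects batch-confounded covariates", {
  x <- mk_matrix(rnorm(8), c("f1", "f2"), paste0("s", 1:4))
  b <- factor(c("A", "A", "B", "B"))
  expect_error(eb_standardize(x, b, covariates = factor(c("t", "t", "u", "u"))),
               "confounded|rank-deficient")
  # unconfounded covariate is accepted
  std <- eb_standardize(x, b, covariates = factor(c("t", "u", "t", "u")))
  expect_identical(dim(std$z), dim(x))
})

test_that("parametric posteriors match an independent fixed-point computation", {
  set.seed(21)
  x <- matrix(rnorm(6 * 10, 20, 1), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  x[, 6:10] <- x[, 6:10] + 2
  b <- factor(rep(c("A", "B"), each = 5))
  std <- eb_standardize(x, b)
  post <- eb_fit_posteriors(std, mode = "parametric")

  for (j in 1:2) {
    lv <- levels(b)[j]
    zb <- std$z[, b == lv, drop = FALSE]
    gh <- rowMeans(zb); dh <- apply(zb, 1, var)
    n <- rowSums(!is.na(zb))
    gbar <- mean(gh); t2 <- var(gh)
    m <- mean(dh); v <- var(dh)
    oracle <- param_fixedpoint_bruteforce(zb, gh, dh, n, gbar, t2,
                                          lambda = m^2 / v + 2,
                                          theta = m^3 / v + m)
    expect_equal(unname(post$gamma_star[, j]), unname(oracle$gamma_star),
                 tolerance = 1e-6)
    expect_equal(unname(post$delta2_star[, j]), unname(oracle$delta2_star),
                 tolerance = 1e-6)
  }

  # shrinkage direction: gamma_star between gamma_hat and gamma_bar in magnitude
  expect_true(all(abs(post$gamma_star) <=
                    pmax(abs(post$gamma_hat),
                         matrix(abs(post$gamma_bar), nrow(x), 2,
                                byrow = TRUE)) + 1e-12))
})

test_that("identical location estimates give a degenerate prior that is returned unshrunken", {
  # two features that are exact location-shifted copies: equal gamma_hat
  x <- mk_matrix(c(1, 2, 3, 4,
                   11, 12, 13, 14), c("f1", "f2"), paste0("s", 1:4))
  b <- factor(c("A", "A", "B", "B"))
  std <- eb_standardize(x, b)
  post <- eb_fit_posteriors(std, mode = "parametric")
  expect_equal(unname(post$tau2), c(0, 0))
  expect_equal(post$gamma_star, post$gamma_hat)
})

test_that("non-parametric posteriors equal brute-force weighted averages and are deterministic", {
  b <- factor(c("A", "A", "A", "B", "B", "B"))
  for (G in 2:5) {
    set.seed(100 + G)
    x <- matrix(rnorm(G * 6, 10, 1), G, 6,
                dimnames = list(paste0("f", 1:G), paste0("s", 1:6)))
    x[, 4:6] <- x[, 4:6] + 1
    if (G >= 3) x[1, 2] <- NA  # exercise available-case likelihoods
    std <- eb_standardize(x, b)
    post <- eb_fit_posteriors(std, mode = "nonparametric")
    oracle <- np_posterior_bruteforce(std$z, std$batch, std$counts)
    expect_equal(unname(post$gamma_star), unname(oracle$gamma_star),
                 tolerance = 1e-10)
    expect_equal(unname(post$delta2_star), unname(oracle$delta2_star),
                 tolerance = 1e-10)
    # bit-identical across repeated runs
    expect_identical(combat_adjust(x, b, mode = "nonparametric"),
                     combat_adjust(x, b, mode = "nonparametric"))
  }
})

test_that("single-feature fallback reproduces the hand-computed adjustments", {
  fx <- single_feature_fixture()
  expect_warning(mo <- combat_adjust(fx$x, fx$batch, mean_only = TRUE),
                 "single-feature")
  expect_equal(as.vector(tapply(mo["p1", ], fx$batch, mean)),
               c(2.5, 2.5), tolerance = 1e-12)
  expect_warning(ls_ <- combat_adjust(fx$x, fx$batch), "single-feature")
  expect_equal(unname(ls_["p1", ]),
               c(2.1464, 2.8536, 2.1464, 2.8536), tolerance = 1e-4)
})

test_that("adjustment preserves the missing mask, shape and ordering", {
  sim <- simulate_batches(n_features = 80, batch_sizes = c(5, 5, 5),
                          mnar_prob = 0, mar_rate = 0.08, seed = 3)
  dis <- dissect(sim$matrix, sim$design)
  g <- dis$groups[[which.max(vapply(dis$groups, function(g)
    length(g$feature_ids), integer(1)))]]
  b <- factor(sim$design$batch[match(g$sample_ids, sim$design$ID)])
  for (mode in c("parametric", "nonparametric")) {
    out <- combat_adjust(g$values, b, mode = mode)
    expect_identical(dimnames(out), dimnames(g$values))
    expect_identical(is.na(out), is.na(g$values))
  }
})

test_that("empirical-Bayes adjustment matches the reference implementation on complete data", {
  skip_if_not_installed("sva")
  set.seed(42)
  x <- matrix(rnorm(50 * 9, 20, 2), 50, 9,
              dimnames = list(paste0("f", 1:50), paste0("s", 1:9)))
  x[, 4:6] <- x[, 4:6] + 3
  x[, 7:9] <- x[, 7:9] * 1.1
  b <- factor(rep(c("A", "B", "C"), each = 3))
  quiet_combat <- function(...) {
    out <- NULL
    invisible(utils::capture.output(
      out <- suppressMessages(sva::ComBat(...)), type = "output"))
    out
  }
  # parametric agreement is bounded by the 1e-4 fixed-point stopping rule
  expect_equal(combat_adjust(x, b, mode = "parametric"),
               quiet_combat(x, batch = b), tolerance = 1e-5)
  expect_equal(combat_adjust(x, b, mode = "nonparametric"),
               quiet_combat(x, batch = b, par.prior = FALSE),
               tolerance = 1e-10)
})

test_that("already batch-free data is nearly unchanged as feature count grows", {
  mean_abs_change <- function(G, seed) {
    sim <- simulate_batches(n_features = G, batch_sizes = c(8, 8),
                            gamma_sd = 0, delta_range = c(1, 1),
                            de_fraction = 0, mnar_prob = 0, mar_rate = 0,
                            seed = seed)
    b <- factor(sim$design$batch[match(colnames(sim$matrix), sim$design$ID)])
    out <- combat_adjust(sim$matrix, b)
    mean(abs(out - sim$matrix))
  }
  small <- mean_abs_change(20, 9)
  big <- mean_abs_change(500, 9)
  expect_lt(big, small)
  expect_lt(big, 0.08)
})
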