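#' Linear-model batch removal for one sub-matrix
#'
#' Per feature, fits by available-case least squares a linear model with an
#' intercept, optional covariate columns, and the batch encoded with
#' sum-to-zero contrasts, then subtracts only the fitted batch component.
#' With sum-to-zero encoding the intercept is the (balanced) grand mean, so
#' removing the batch component re-centers every batch on it — the same
#' semantics as the classic linear batch-removal of expression matrices, here
#' tolerant of scattered missing cells. Covariate (treatment) effects are
#' never removed.
#'
#' @param x Numeric sub-matrix (features x samples, `NA` = missing); every
#'   (feature, batch) block needs >= 2 observed values.
#' @param batch Factor of batch labels aligned to columns; >= 2 levels.
#' @param covariates Optional per-sample covariates to protect (vector,
#'   factor, data.frame or matrix).
#' @return Corrected matrix, same shape/dimnames; missing cells stay missing.
#' @examples
#' x <- matrix(c(1, 2, 3, 4), 1, 4,
#'             dimnames = list("p1", paste0("s", 1:4)))
#' remove_batch_linear(x, factor(c("A", "A", "B", "B")))  # 2 3 2 3
#' @export
remove_batch_linear <- function(x, batch, covariates = NULL) {
  batch <- droplevels(as.factor(batch))
  stopifnot(is.matrix(x), length(batch) == ncol(x))
  if (nlevels(batch) < 2L) stop("need >= 2 batches")
  B <- stats::model.matrix(~ batch,
                           contrasts.arg = list(batch = "contr.sum"))
  cm <- covariate_matrix(covariates, colnames(x))
  X <- if (is.null(cm)) B else cbind(B, cm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  batch_cols <- 1L + seq_len(nlevels(batch) - 1L)  # after the intercept
  out <- x
  for (g in seq_len(nrow(x))) {
    ok <- !is.na(x[g, ])
    fit <- stats::lm.fit(X[ok, , drop = FALSE], x[g, ok])
    beta <- fit$coefficients
    if (anyNA(beta))
      stop("rank-deficient available-case design for feature ", rownames(x)[g])
    batch_component <- as.vector(X[, batch_cols, drop = FALSE] %*%
                                   beta[batch_cols])
    out[g, ] <- x[g, ] - batch_component
  }
  out
}
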