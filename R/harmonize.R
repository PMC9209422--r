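#' Harmonize batch effects in an incomplete abundance matrix
#'
#' The main entry point. The matrix is dissected into sub-matrices of features
#' sharing a batch-presence pattern ([dissect()]); each sub-matrix is corrected
#' independently — empirical-Bayes location/scale adjustment
#' ([combat_adjust()]) or linear-model batch removal ([remove_batch_linear()])
#' — and the corrected pieces are rejoined into the original layout
#' ([rejoin()]). Features observed in fewer than two batches pass through
#' unchanged; no cell is ever imputed. Group corrections are independent work
#' units and can run in parallel; the result is bit-identical for any worker
#' count.
#'
#' A group whose correction fails (e.g. a pathological pattern) is passed
#' through unchanged and reported in `report$warnings` rather than aborting
#' the run.
#'
#' @param x Abundance matrix (features x samples, `NA` = missing), e.g. from
#'   [read_abundance()].
#' @param design A `batch_design` (see [read_design()], [as_batch_design()]).
#' @param algorithm `"eb"` (empirical Bayes, the default), `"linear"`
#'   (linear-model removal), or `"identity"` (no correction; diagnostic
#'   round-trip mode).
#' @param mode EB flavor: `"parametric"` or `"nonparametric"`.
#' @param mean_only EB only: adjust location but not scale.
#' @param min_per_batch Minimum observed values for a batch to count as
#'   present for a feature (default 2).
#' @param keep_singletons Keep a grouped feature's stray values in batches
#'   outside its pattern instead of blanking them (see [rejoin()]).
#' @param covariates Optional per-sample covariates (treatment structure)
#'   preserved through correction.
#' @param workers Number of parallel workers (forked; >1 is ignored on
#'   platforms without fork support).
#' @return An object of class `harmonization`: a list with `corrected` (the
#'   harmonized matrix, same shape/dimnames as `x`), `report` (counts, the
#'   pattern histogram, flags and any group warnings) and `call`.
#' @examples
#' sim <- simulate_batches(n_features = 60, batch_sizes = c(4, 4),
#'                         seed = 1, mnar_prob = 0, mar_rate = 0)
#' h <- harmonize(sim$matrix, sim$design, algorithm = "linear")
#' h
#' @export
harmonize <- function(x, design,
                      algorithm = c("eb", "linear", "identity"),
                      mode = c("parametric", "nonparametric"),
                      mean_only = FALSE, min_per_batch = 2L,
                      keep_singletons = FALSE, covariates = NULL,
                      workers = 1L) {
  algorithm <- match.arg(algorithm)
  mode <- match.arg(mode)
  validate_inputs(x, design)
  b_all <- batch_factor(x, design)
  names(b_all) <- colnames(x)

  dis <- dissect(x, design, min_per_batch)
  corrector <- switch(algorithm,
    identity = function(vals, batch) vals,
    linear = function(vals, batch)
      remove_batch_linear(vals, batch, covariates = sub_covariates(
        covariates, colnames(vals), colnames(x))),
    eb = function(vals, batch)
      combat_adjust(vals, batch, mode = mode, mean_only = mean_only,
                    covariates = sub_covariates(
                      covariates, colnames(vals), colnames(x))))

  res <- parallel_map(dis$groups, corrector, b_all, workers)
  corrected_groups <- res$groups

  rj <- rejoin(corrected_groups, dis$passthrough, x, design,
               keep_singletons = keep_singletons)

  hist_labels <- vapply(dis$groups, function(g)
    paste(g$batches, collapse = ";"), character(1L))
  report <- list(
    n_features_total = nrow(x),
    n_features_corrected = nrow(x) - length(dis$passthrough),
    n_features_passthrough = length(dis$passthrough),
    n_groups = length(dis$groups),
    n_batches = nlevels(b_all),
    pattern_histogram = stats::setNames(
      vapply(dis$groups, function(g) length(g$feature_ids), integer(1L)),
      hist_labels),
    n_singleton_cells_discarded = rj$n_singleton_cells_discarded,
    algorithm = algorithm, mode = mode, mean_only = mean_only,
    min_per_batch = min_per_batch, keep_singletons = keep_singletons,
    workers = workers,
    warnings = res$warnings)
  structure(list(corrected = rj$matrix, report = report,
                 call = match.call()),
            class = "harmonization")
}

# subset per-sample covariates to a group's columns
sub_covariates <- function(covariates, cols, all_cols) {
  if (is.null(covariates)) return(NULL)
  idx <- match(cols, all_cols)
  if (is.vector(covariates) || is.factor(covariates)) {
    if (length(covariates) != length(all_cols))
      stop("covariates must have one entry per sample")
    return(covariates[idx])
  }
  covariates[idx, , drop = FALSE]
}

#' Apply a corrector to every sub-matrix group, optionally in parallel
#'
#' Groups are scheduled largest-first for load balance, corrected
#' independently, and re-sorted into the deterministic [dissect()] order, so
#' results are bit-identical for `workers = 1` and `workers = k`. A failing
#' group is returned unchanged and its error message collected.
#'
#' @param groups List of groups from [dissect()].
#' @param corrector `function(values, batch)` returning a corrected matrix of
#'   identical shape.
#' @param batch_all Batch factor aligned to the full matrix columns.
#' @param workers Number of forked workers (>= 1).
#' @return List with `groups` (corrected, original order) and `warnings`
#'   (character vector of per-group failure messages, possibly empty).
#' @export
parallel_map <- function(groups, corrector, batch_all, workers = 1L) {
  stopifnot(workers >= 1L)
  if (!length(groups)) return(list(groups = list(), warnings = character(0)))
  sizes <- vapply(groups, function(g)
    length(g$feature_ids) * length(g$sample_ids), numeric(1L))
  sched <- order(sizes, decreasing = TRUE)

  run_one <- function(i) {
    g <- groups[[i]]
    b <- droplevels(batch_all[match(g$sample_ids, names(batch_all))])
    out <- tryCatch(
      list(values = suppressWarnings(corrector(g$values, b)), error = NULL),
      error = function(e)
        list(values = g$values,
             error = sprintf("group [%s]: %s",
                             paste(g$batches, collapse = ";"),
                             conditionMessage(e))))
    out
  }
  if (is.null(names(batch_all)))
    stop("batch_all must be named by sample id")

  use_fork <- workers > 1L && .Platform$OS.type == "unix"
  results <- if (use_fork)
    parallel::mclapply(sched, run_one, mc.cores = workers)
  else lapply(sched, run_one)

  warnings <- character(0)
  out_groups <- groups
  for (k in seq_along(sched)) {
    i <- sched[k]
    r <- results[[k]]
    if (inherits(r, "try-error") || is.null(r$values)) {
      warnings <- c(warnings, sprintf("group [%s]: worker failure",
                                      paste(groups[[i]]$batches,
                                            collapse = ";")))
      next
    }
    out_groups[[i]]$values <- r$values
    if (!is.null(r$error)) warnings <- c(warnings, r$error)
  }
  list(groups = out_groups, warnings = warnings)
}

#' @export
print.harmonization <- function(x, ...) {
  r <- x$report
  cat("Batch harmonization (", r$algorithm,
      if (r$algorithm == "eb") paste0("/", r$mode,
                                      if (r$mean_only) ", mean-only" else ""),
      ")\n", sep = "")
  cat(sprintf("  %d features x %d samples, %d batches\n",
              r$n_features_total, ncol(x$corrected), r$n_batches))
  cat(sprintf("  corrected: %d features in %d pattern group(s); passthrough: %d\n",
              r$n_features_corrected, r$n_groups, r$n_features_passthrough))
  if (r$n_singleton_cells_discarded > 0)
    cat(sprintf("  singleton cells discarded: %d\n",
                r$n_singleton_cells_discarded))
  if (length(r$warnings))
    cat("  warnings:", length(r$warnings), "group(s) passed through uncorrected\n")
  invisible(x)
}

#' @export
summary.harmonization <- function(object, ...) {
  r <- object$report
  print(object)
  cat("\nPattern histogram (features per batch-presence pattern):\n")
  h <- r$pattern_histogram
  if (length(h)) {
    for (i in seq_along(h))
      cat(sprintf("  {%s}: %d\n", names(h)[i], h[i]))
  } else cat("  (no correctable group)\n")
  if (length(r$warnings)) {
    cat("\nGroup warnings:\n")
    for (w in r$warnings) cat("  -", w, "\n")
  }
  invisible(r)
}

#' Diagnostic plot of a harmonization
#'
#' Per-sample means and coefficients of variation grouped by batch, before
#' (if `before` is supplied) and after correction — the standard visual check
#' that batch-level location differences were removed.
#'
#' @param x A `harmonization` object.
#' @param design The `batch_design` used for the run.
#' @param before Optional uncorrected matrix for side-by-side comparison.
#' @param ... Passed to [boxplot()].
#' @export
plot.harmonization <- function(x, design, before = NULL, ...) {
  b <- batch_factor(x$corrected, design)
  panels <- if (is.null(before)) 1L else 2L
  op <- graphics::par(mfrow = c(1L, panels))
  on.exit(graphics::par(op))
  if (!is.null(before)) {
    s0 <- sample_stats(before)
    graphics::boxplot(s0$mean ~ b, xlab = "batch", ylab = "sample mean",
                      main = "before", ...)
  }
  s1 <- sample_stats(x$corrected)
  graphics::boxplot(s1$mean ~ b, xlab = "batch", ylab = "sample mean",
                    main = "after", ...)
  invisible(x)
}

#' Export a harmonization report as JSON
#'
#' @param x A `harmonization` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  stopifnot(inherits(x, "harmonization"))
  jsonlite::write_json(x$report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
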