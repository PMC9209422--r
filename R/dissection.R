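#' Batch-presence patterns of every feature
#'
#' A batch is "present" for a feature when the feature has at least
#' `min_per_batch` observed (non-missing) values among that batch's samples;
#' with fewer values no within-batch variance can be estimated and the feature
#' is treated as missing from that batch. Features present in fewer than two
#' batches cannot be harmonized and are passed through untouched.
#'
#' @param x Abundance matrix (features x samples, `NA` = missing).
#' @param design A `batch_design` covering the matrix columns.
#' @param min_per_batch Minimum observed values per batch (default 2).
#' @return Logical matrix features x batches (batch columns in sorted label
#'   order): `TRUE` where the batch is present for the feature.
#' @export
presence_patterns <- function(x, design, min_per_batch = 2L) {
  stopifnot(min_per_batch >= 1L)
  b <- batch_factor(x, design)
  counts <- vapply(levels(b), function(lv)
    rowSums(!is.na(x[, b == lv, drop = FALSE])), numeric(nrow(x)))
  if (nrow(x) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(rownames(x), levels(b)))
  counts >= min_per_batch
}

#' Dissect a matrix into presence-pattern sub-matrices
#'
#' Groups features by identical batch-presence pattern. Each group holds the
#' member features (input order preserved) restricted to the sample columns of
#' its present batches; it is the unit of batch correction. Features present
#' in at most one batch go to `passthrough`. Groups are ordered
#' lexicographically by their sorted batch-label tuple, so the result is
#' deterministic regardless of feature order or worker count.
#'
#' @inheritParams presence_patterns
#' @return List with `groups` (each a list with `batches`, `feature_ids`,
#'   `sample_ids`, `values`) and `passthrough` (character vector of feature ids).
#' @export
dissect <- function(x, design, min_per_batch = 2L) {
  pres <- presence_patterns(x, design, min_per_batch)
  b <- batch_factor(x, design)
  n_present <- rowSums(pres)
  correctable <- n_present >= 2L
  passthrough <- rownames(x)[!correctable]

  groups <- list()
  if (any(correctable)) {
    keys <- apply(pres[correctable, , drop = FALSE], 1L, function(r)
      paste(colnames(pres)[r], collapse = "\x1f"))
    feats <- rownames(x)[correctable]
    split_feats <- split(feats, keys)
    # lexicographic over the sorted batch-label tuples
    ord <- order(names(split_feats))
    groups <- lapply(names(split_feats)[ord], function(key) {
      batches <- strsplit(key, "\x1f", fixed = TRUE)[[1L]]
      cols <- colnames(x)[b %in% batches]
      fids <- split_feats[[key]]
      list(batches = batches,
           feature_ids = fids,
           sample_ids = cols,
           values = x[fids, cols, drop = FALSE])
    })
  }
  list(groups = groups, passthrough = passthrough)
}

#' Upper bound on the number of correctable sub-matrices
#'
#' With `n` batches, a correctable sub-matrix corresponds to a subset of two
#' or more batches, so at most `sum(choose(n, 2:n)) = 2^n - n - 1` distinct
#' sub-matrices can arise. In practice far fewer patterns are realized, since
#' the bound quickly exceeds the number of features in any real dataset.
#'
#' @param n Number of batches (non-negative integer).
#' @return The exact count as a double (integer-valued; exact for `n <= 64`
#'   would overflow 32-bit integers, so double arithmetic on the closed form
#'   is used, exact up to 2^53).
#' @examples
#' max_submatrix_count(3)   # 4
#' max_submatrix_count(20)  # 1048555
#' @export
max_submatrix_count <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("n must be a single non-negative integer")
  if (n < 2) return(0)
  2^n - n - 1
}

#' Rejoin corrected sub-matrices into the template layout
#'
#' Writes every group's (corrected) values back into a matrix with the
#' template's exact feature and sample ordering, and copies passthrough
#' features verbatim. Cells of a grouped feature that sit in batches outside
#' its presence pattern hold at most `min_per_batch - 1` stray values
#' ("singletons" at the default threshold); by default they are set to missing,
#' because a single value admits no variance estimate and would mix corrected
#' and uncorrected scales. `keep_singletons = TRUE` retains them uncorrected.
#'
#' @param groups List of groups as returned by [dissect()] (values possibly
#'   corrected; shape and dimnames must be unchanged).
#' @param template The original matrix: supplies shape, ordering and the
#'   passthrough/singleton cell values.
#' @param design A `batch_design`.
#' @param passthrough Character vector of uncorrected feature ids.
#' @param keep_singletons Keep values outside a grouped feature's pattern.
#' @return List with `matrix` (same dimnames as `template`) and
#'   `n_singleton_cells_discarded`.
#' @export
rejoin <- function(groups, passthrough, template, design,
                   keep_singletons = FALSE) {
  covered <- c(unlist(lapply(groups, `[[`, "feature_ids")), passthrough)
  if (anyDuplicated(covered))
    stop("feature(s) covered more than once: ",
         paste(unique(covered[duplicated(covered)]), collapse = ", "))
  absent <- setdiff(rownames(template), covered)
  if (length(absent) || length(setdiff(covered, rownames(template))))
    stop("groups + passthrough do not cover the template features exactly; ",
         "missing: [", paste(absent, collapse = ", "), "]")

  out <- template
  b <- batch_factor(template, design)
  n_discarded <- 0L
  for (g in groups) {
    if (!identical(dim(g$values),
                   c(length(g$feature_ids), length(g$sample_ids))))
      stop("group value dimensions changed for pattern ",
           paste(g$batches, collapse = ";"))
    outside_cols <- colnames(template)[!(b %in% g$batches)]
    if (length(outside_cols) && !keep_singletons) {
      stray <- !is.na(template[g$feature_ids, outside_cols, drop = FALSE])
      n_discarded <- n_discarded + sum(stray)
      out[g$feature_ids, outside_cols] <- NA_real_
    }
    out[g$feature_ids, g$sample_ids] <- g$values
  }
  list(matrix = out, n_singleton_cells_discarded = n_discarded)
}

#' Write a feature-to-pattern report
#'
#' @param x,design,min_per_batch As in [dissect()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(x, design, path, min_per_batch = 2L) {
  dis <- dissect(x, design, min_per_batch)
  rows <- character(0)
  for (i in seq_along(dis$groups)) {
    g <- dis$groups[[i]]
    rows <- c(rows, paste(g$feature_ids,
                          paste(g$batches, collapse = ";"), i, sep = "\t"))
  }
  if (length(dis$passthrough))
    rows <- c(rows, paste(dis$passthrough, "", NA, sep = "\t"))
  writeLines(c("ID\tpattern\tgroup", rows), path)
  invisible(path)
}
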