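#' Read an abundance matrix from tab-separated text
#'
#' Reads a features-by-samples abundance matrix: a header row of sample
#' identifiers, a first column of feature identifiers, and tab-separated
#' numeric cells. Cells matching one of `missing_tokens` (case-insensitive)
#' become `NA`. Row and column order are preserved exactly as in the file.
#'
#' @param path Path to a TSV file. The first header field is the feature-id
#'   column name (conventionally `"ID"`) and is not a sample.
#' @param missing_tokens Character vector of cell values treated as missing,
#'   compared case-insensitively. The empty string is always included.
#' @return A numeric matrix with feature ids as `rownames` and sample ids as
#'   `colnames`; missing cells are `NA`.
#' @seealso [write_abundance()], [read_design()], [validate_inputs()]
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("ID\ts1\ts2", "p1\t1.5\tNA", "p2\t2\t3"), tf)
#' m <- read_abundance(tf)
#' sum(is.na(m))  # 1
#' @export
read_abundance <- function(path, missing_tokens = c("", "NA", "NaN")) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) < 1L || ncol(raw) < 2L)
    stop("matrix file must have a header row and at least one sample column")
  sample_ids <- as.character(raw[1L, -1L])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample id(s) in header: ", paste(unique(dup), collapse = ", "))
  body <- raw[-1L, , drop = FALSE]
  feature_ids <- as.character(body[[1L]])
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  cells <- as.matrix(body[, -1L, drop = FALSE])
  tokens <- unique(c("", tolower(missing_tokens)))
  miss <- tolower(cells) %in% tokens | is.na(cells)
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(!miss & (is.na(vals) | !is.finite(vals)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(cells)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(cells)) + 1L
    stop(sprintf("unparseable cell '%s' at feature '%s' (row %d), sample '%s' (column %d)",
                 cells[bad[1L]], feature_ids[i], i, sample_ids[j], j))
  }
  vals[miss] <- NA_real_
  m <- matrix(vals, nrow = length(feature_ids),
              dimnames = list(feature_ids, sample_ids))
  m
}

#' Write an abundance matrix as tab-separated text
#'
#' Inverse of [read_abundance()]: header row of sample ids, first column of
#' feature ids, missing cells written as `"NA"`. `read_abundance(write_abundance(m))`
#' reproduces `m` exactly.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file path.
#' @param id_column Name of the feature-id header field.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path, id_column = "ID") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  header <- paste(c(id_column, colnames(x)), collapse = "\t")
  body <- vapply(seq_len(nrow(x)), function(i) {
    cells <- format(x[i, ], trim = TRUE, digits = 15)
    cells[is.na(x[i, ])] <- "NA"
    paste(c(rownames(x)[i], cells), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a batch description table
#'
#' Reads the CSV convention `ID,sample,batch`: one row per sample, `ID` the
#' sample identifier matching the matrix header, `sample` its 1-based column
#' position, and `batch` an arbitrary batch label. Column names are
#' configurable for other exports.
#'
#' @param path Path to a CSV file.
#' @param columns Length-3 character vector naming the id, order and batch
#'   columns in the file, in that order.
#' @return A `data.frame` of class `batch_design` with columns `ID` (character),
#'   `sample` (integer order) and `batch` (character, kept verbatim).
#' @export
read_design <- function(path, columns = c("ID", "sample", "batch")) {
  stopifnot(length(columns) == 3L)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(columns, names(d))
  if (length(missing_cols))
    stop("design file lacks column(s): ", paste(missing_cols, collapse = ", "),
         " (found: ", paste(names(d), collapse = ", "), ")")
  as_batch_design(ids = as.character(d[[columns[1L]]]),
                  order = d[[columns[2L]]],
                  batch = as.character(d[[columns[3L]]]))
}

#' Construct a batch design in code
#'
#' @param ids Character vector of sample identifiers (unique).
#' @param batch Batch label per sample.
#' @param order Optional 1-based column positions; defaults to `seq_along(ids)`.
#' @return A `batch_design` data.frame; see [read_design()].
#' @export
as_batch_design <- function(ids, batch, order = seq_along(ids)) {
  ids <- as.character(ids)
  batch <- as.character(batch)
  if (anyDuplicated(ids))
    stop("duplicate sample id(s) in design: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(batch) != length(ids) || length(order) != length(ids))
    stop("ids, order and batch must have equal length")
  ord <- suppressWarnings(as.integer(order))
  if (anyNA(ord) || !setequal(ord, seq_along(ids)))
    stop("order column is not a permutation of 1..", length(ids))
  d <- data.frame(ID = ids, sample = ord, batch = batch,
                  stringsAsFactors = FALSE)
  class(d) <- c("batch_design", "data.frame")
  d
}

#' Check matrix/design consistency and summarize the inputs
#'
#' Asserts that the design's sample ids and the matrix's column names are the
#' same set, and that every batch has at least one sample. Returns a small
#' report rather than printing.
#'
#' @param x Abundance matrix (see [read_abundance()]).
#' @param design A `batch_design` (see [read_design()]).
#' @return A list with `n_features`, `n_samples`, `batch_sizes` (named integer
#'   vector, batches in sorted label order) and `missing_fraction`.
#' @export
validate_inputs <- function(x, design) {
  stopifnot(is.matrix(x))
  mat_ids <- colnames(x)
  extra_design <- setdiff(design$ID, mat_ids)
  extra_matrix <- setdiff(mat_ids, design$ID)
  if (length(extra_design) || length(extra_matrix))
    stop("sample sets differ between matrix and design; ",
         "only in design: [", paste(extra_design, collapse = ", "), "]; ",
         "only in matrix: [", paste(extra_matrix, collapse = ", "), "]")
  sizes <- table(design$batch)
  list(n_features = nrow(x),
       n_samples = ncol(x),
       batch_sizes = stats::setNames(as.integer(sizes), names(sizes)),
       missing_fraction = mean(is.na(x)))
}

# Batch label per matrix column, aligned to colnames(x); levels in sorted
# label order so that downstream ordering never depends on file row order.
batch_factor <- function(x, design) {
  b <- design$batch[match(colnames(x), design$ID)]
  factor(b, levels = sort(unique(design$batch)))
}
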