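#' Validate a non-negative expression matrix
#'
#' Checks the container invariants every matrix entering a factorization
#' must satisfy: a dense numeric matrix, at least 1 x 1, all entries finite
#' and non-negative, and any row/column names matching the dimensions.
#'
#' @param M a numeric matrix, optionally with dimnames.
#' @param what label used in error messages.
#' @return `M`, invisibly, if valid; otherwise a classed error is raised.
#' @export
validate_matrix <- function(M, what = "matrix") {
  if (!is.matrix(M) || !is.numeric(M))
    bnmf_domain_error(sprintf("%s must be a numeric matrix", what))
  if (nrow(M) < 1L || ncol(M) < 1L)
    bnmf_dim_error(sprintf("%s must have at least one row and one column", what))
  if (any(!is.finite(M)))
    bnmf_domain_error(sprintf("%s contains non-finite values", what))
  if (any(M < 0))
    bnmf_domain_error(sprintf("non-negative input required: %s has negative entries", what))
  invisible(M)
}

num_or_na <- function(x) suppressWarnings(as.numeric(x))

#' Read a tab-separated expression matrix
#'
#' Parses the tab-separated text format: numeric cells separated by single
#' tabs, with an optional single header row of column labels and an optional
#' leading column of row labels. When a label flag is `NA` (the default) its
#' presence is auto-detected: a non-numeric first row means column labels, a
#' non-numeric first data field means row labels.
#'
#' @param path path to the file.
#' @param has_row_labels,has_col_labels logical or `NA` (auto-detect).
#' @return a numeric matrix; labels, when present, become `rownames`/
#'   `colnames`.
#' @export
read_matrix_tsv <- function(path, has_row_labels = NA, has_col_labels = NA) {
  if (!file.exists(path)) bnmf_io_error(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  # tolerate blank trailing line(s)
  while (length(lines) > 0L && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (length(lines) == 0L) bnmf_format_error(sprintf("empty file: %s", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)

  if (is.na(has_col_labels)) {
    first <- num_or_na(cells[[1L]])
    has_col_labels <- anyNA(first)
  }
  col_labels <- NULL
  if (has_col_labels) {
    if (length(cells) < 2L)
      bnmf_format_error("header row present but no data rows")
    col_labels <- cells[[1L]]
    cells <- cells[-1L]
  }
  if (is.na(has_row_labels)) {
    has_row_labels <- is.na(num_or_na(cells[[1L]][1L]))
  }

  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    bnmf_format_error(sprintf(
      "ragged rows: data row %d has %d fields, expected %d",
      which(widths != widths[1L])[1L], widths[widths != widths[1L]][1L], widths[1L]))

  row_labels <- NULL
  if (has_row_labels) {
    row_labels <- vapply(cells, `[`, character(1L), 1L)
    cells <- lapply(cells, `[`, -1L)
  }
  n <- length(cells)
  m <- length(cells[[1L]])
  if (m < 1L) bnmf_format_error("no data columns found")
  if (!is.null(col_labels)) {
    # header may or may not carry a corner cell above the row-label column
    if (has_row_labels && length(col_labels) == m + 1L) col_labels <- col_labels[-1L]
    if (length(col_labels) != m)
      bnmf_format_error(sprintf(
        "header has %d labels for %d data columns", length(col_labels), m))
  }

  vals <- num_or_na(unlist(cells, use.names = FALSE))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    r <- (bad - 1L) %/% m + 1L
    c <- (bad - 1L) %% m + 1L
    bnmf_parse_error(sprintf("non-numeric value at data row %d, column %d", r, c))
  }
  M <- matrix(vals, nrow = n, ncol = m, byrow = TRUE)
  if (!is.null(row_labels)) rownames(M) <- row_labels
  if (!is.null(col_labels)) colnames(M) <- col_labels
  validate_matrix(M, sprintf("matrix read from %s", path))
  M
}

#' Write a matrix as tab-separated text
#'
#' Inverse of [read_matrix_tsv()]: values are printed with `%.17g` so a
#' read/write round trip reproduces doubles exactly; row/column names, when
#' present, are written as a label column and header row.
#'
#' @param M validated numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  validate_matrix(M)
  body <- apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  if (!is.null(rownames(M)))
    body <- paste(rownames(M), body, sep = "\t")
  lines <- body
  if (!is.null(colnames(M))) {
    header <- paste(colnames(M), collapse = "\t")
    if (!is.null(rownames(M))) header <- paste0("\t", header)
    lines <- c(header, body)
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) bnmf_io_error(sprintf("cannot write to %s", path))
  invisible(path)
}

element_size <- function(precision = c("double", "single")) {
  switch(match.arg(precision), double = 8L, single = 4L)
}

#' Read an IEEE little-endian binary matrix
#'
#' The payload is the matrix in row-major order as little-endian IEEE 754
#' floats of the stated precision. Two dialects exist: `"headered"` (the
#' default) prefixes the payload with the dimensions as two little-endian
#' unsigned 32-bit integers; `"raw"` has no header and the caller supplies
#' `n_rows`/`n_cols`.
#'
#' @param path path to the file.
#' @param n_rows,n_cols dimensions; required for the raw dialect, checked
#'   against the header otherwise when supplied.
#' @param precision `"double"` (8-byte) or `"single"` (4-byte) elements.
#' @param header logical; `TRUE` for the headered dialect.
#' @return an unlabeled numeric matrix.
#' @export
read_matrix_bin <- function(path, n_rows = NULL, n_cols = NULL,
                            precision = c("double", "single"), header = TRUE) {
  precision <- match.arg(precision)
  if (!file.exists(path)) bnmf_io_error(sprintf("file not found: %s", path))
  es <- element_size(precision)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  if (header) {
    if (sz < 8) bnmf_format_error("file too short for dimension header")
    dims <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
    if (any(dims < 1L))
      bnmf_format_error("invalid dimension header")
    if (!is.null(n_rows) && n_rows != dims[1L])
      bnmf_format_error(sprintf("header says %d rows, caller expected %d", dims[1L], n_rows))
    if (!is.null(n_cols) && n_cols != dims[2L])
      bnmf_format_error(sprintf("header says %d cols, caller expected %d", dims[2L], n_cols))
    n_rows <- dims[1L]; n_cols <- dims[2L]
    payload <- sz - 8
  } else {
    if (is.null(n_rows) || is.null(n_cols))
      bnmf_config_error("raw binary dialect requires n_rows and n_cols")
    payload <- sz
  }
  expected <- as.numeric(n_rows) * n_cols * es
  if (payload != expected)
    bnmf_format_error(sprintf(
      "size mismatch: %d payload bytes, expected %d for %d x %d %s",
      payload, expected, n_rows, n_cols, precision))
  vals <- readBin(con, "double", n = n_rows * n_cols, size = es, endian = "little")
  if (any(!is.finite(vals)))
    bnmf_domain_error("binary payload contains NaN or Inf")
  if (any(vals < 0))
    bnmf_domain_error("non-negative input required: binary payload has negative values")
  matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
}

#' Write a matrix as IEEE little-endian binary
#'
#' @inheritParams read_matrix_bin
#' @param M validated numeric matrix; labels are not stored in this format.
#' @return `path`, invisibly.
#' @export
write_matrix_bin <- function(M, path, precision = c("double", "single"),
                             header = TRUE) {
  precision <- match.arg(precision)
  validate_matrix(M)
  es <- element_size(precision)
  con <- tryCatch(file(path, "wb"), error = function(e)
    bnmf_io_error(sprintf("cannot write to %s", path)))
  on.exit(close(con))
  if (header)
    writeBin(as.integer(dim(M)), con, size = 4L, endian = "little")
  writeBin(as.vector(t(M)), con, size = es, endian = "little")
  invisible(path)
}
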