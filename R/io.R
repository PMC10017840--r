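#' Read a labelled numeric matrix from delimited text
#'
#' Expects a header row of feature ids and a first column of row ids. The
#' delimiter is auto-detected from the file extension (`.csv` = comma,
#' anything else = tab) unless given explicitly. Parse problems — ragged
#' rows, non-numeric cells, duplicate labels — raise errors naming the
#' offending line.
#'
#' @param path Path to the file.
#' @param expect_square Require a square matrix.
#' @param expect_symmetric Require symmetry within `1e-8` (implies square).
#' @param sep Field separator; `NULL` for extension-based detection.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix <- function(path, expect_square = FALSE, expect_symmetric = FALSE,
                        sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop(sprintf("'%s' has no data rows", path))

  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  col_ids <- header[-1]
  n_col <- length(col_ids)
  if (n_col < 1) stop(sprintf("'%s' line 1: header has no feature columns", path))
  if (anyDuplicated(col_ids))
    stop(sprintf("'%s' line 1: duplicate column labels", path))

  n_row <- length(fields) - 1L
  values <- matrix(NA_real_, n_row, n_col)
  row_ids <- character(n_row)
  for (i in seq_len(n_row)) {
    f <- fields[[i + 1L]]
    if (length(f) != n_col + 1L)
      stop(sprintf("'%s' line %d: expected %d fields, found %d",
                   path, i + 1L, n_col + 1L, length(f)))
    row_ids[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (any(is.na(v))) {
      bad <- which(is.na(v))[1]
      stop(sprintf("'%s' line %d: non-numeric cell in column '%s'",
                   path, i + 1L, col_ids[bad]))
    }
    values[i, ] <- v
  }
  if (anyDuplicated(row_ids))
    stop(sprintf("'%s': duplicate row labels", path))
  dimnames(values) <- list(row_ids, col_ids)

  if ((expect_square || expect_symmetric) && n_row != n_col)
    stop(sprintf("'%s': expected a square matrix, got %d x %d",
                 path, n_row, n_col))
  if (expect_symmetric && max(abs(values - t(values))) > 1e-8)
    stop(sprintf("'%s': matrix is not symmetric within 1e-8", path))
  values
}

#' Write a labelled numeric matrix as delimited text
#'
#' Inverse of [read_matrix()]: header row of column ids (first header cell
#' `"id"`), first column of row ids, values printed to 12 significant
#' digits so a round-trip is exact to printed precision.
#'
#' @param x Numeric matrix (dimnames generated if missing).
#' @param path Output path; extension selects the delimiter as in
#'   [read_matrix()].
#' @param sep Field separator; `NULL` for extension-based detection.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, sep = NULL) {
  x <- as.matrix(x)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  if (is.null(rownames(x))) rownames(x) <- paste0("R", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("C", seq_len(ncol(x)))
  lines <- c(paste(c("id", colnames(x)), collapse = sep),
             vapply(seq_len(nrow(x)), function(i) {
               paste(c(rownames(x)[i], formatC(x[i, ], format = "g", digits = 12)),
                     collapse = sep)
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
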