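#' Read a tab-delimited numeric matrix
#'
#' Reads a rectangular, headerless, tab-delimited numeric matrix as written by
#' [write_matrix()]. Ragged rows and non-numeric cells are reported with their
#' line number.
#'
#' @param path Path to a tab-delimited text file.
#' @return A numeric matrix.
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stop("empty matrix file: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != ncols[1])) {
    bad <- which(ncols != ncols[1])[1]
    stop("ragged row in ", path, " at line ", bad, ": expected ",
         ncols[1], " fields, found ", ncols[bad])
  }
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- which(vapply(vals, anyNA, logical(1)))
  if (length(bad) > 0) {
    stop("non-numeric cell in ", path, " at line ", bad[1])
  }
  matrix(unlist(vals), nrow = length(vals), ncol = ncols[1], byrow = TRUE)
}

#' Write a numeric matrix as tab-delimited text
#'
#' Writes at full double precision (17 significant digits) so that
#' `read_matrix(write_matrix(m, path))` reproduces `m` exactly.
#'
#' @param m Numeric matrix or vector (a vector is written as one column).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (is.vector(m)) m <- matrix(m, ncol = 1)
  stopifnot(is.matrix(m), is.numeric(m))
  lines <- apply(m, 1, function(row) paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
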