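#' Write a data frame as a TSV file
#'
#' Tab-separated, no quoting, no row names, `NA` as empty string — the
#' fixed serialisation used for every pipeline table so reruns are
#' byte-identical.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a TSV file written by [write_tsv()]
#'
#' @param path Input path.
#' @return Data frame; empty fields become `NA`.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = c("", "NA"), check.names = FALSE)
}

#' Write a numeric matrix as a TSV with an id column
#'
#' First column holds the row ids (header `id`), remaining columns the
#' matrix columns. [read_matrix_tsv()] inverts it.
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a matrix TSV written by [write_matrix_tsv()]
#'
#' @param path Input path.
#' @return Numeric matrix with row and column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
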