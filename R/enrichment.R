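#' Hypergeometric overrepresentation analysis
#'
#' Tests each term set for overrepresentation in a hit list against a gene
#' universe with the one-sided hypergeometric upper tail
#' \eqn{p = \sum_{k \ge x} C(K,k) C(N-K, n-k) / C(N,n)} where `N` is the
#' universe size, `K` the term size within the universe, `n` the hit-list
#' size and `x` the observed hits. P-values are BH-adjusted across all
#' tested terms; rows come back sorted by ascending raw p.
#'
#' The `ease` variant discounts one hit per term (x replaced by x - 1; a
#' term with a single hit scores p = 1), the conservative modification
#' popularised by the DAVID service.
#'
#' @param hits Character vector of hit gene symbols (subset of `universe`).
#' @param terms Term collection from [read_gmt()] (list of character
#'   vectors named by term id, with a `"names"` attribute of descriptions).
#' @param universe Character vector of background gene symbols.
#' @param ease Use the EASE-style discounted count (default `FALSE`).
#' @return Data frame: `term`, `name`, `x` (hits), `n` (list size), `K`
#'   (term size), `N` (universe size), `p`, `q`.
#' @export
enrich <- function(hits, terms, universe, ease = FALSE) {
  universe <- unique(universe)
  hits <- unique(hits)
  if (length(universe) == 0L) stop("enrich: empty universe")
  if (length(hits) == 0L) stop("enrich: empty hit list")
  if (!all(hits %in% universe)) {
    stop("enrich: hit list must be a subset of the universe")
  }
  nn <- length(universe)
  n <- length(hits)
  term_names <- attr(terms, "names_desc")
  rows <- lapply(names(terms), function(id) {
    members <- intersect(terms[[id]], universe)
    big_k <- length(members)
    x <- length(intersect(members, hits))
    x_eff <- if (ease) max(x - 1L, 0L) else x
    p <- if (ease && x_eff == 0L) 1 else
      stats::phyper(x_eff - 1L, big_k, nn - big_k, n, lower.tail = FALSE)
    data.frame(term = id,
               name = if (!is.null(term_names)) term_names[[id]] else id,
               x = x, n = n, K = big_k, N = nn, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT semantics: one term per line, tab-separated — term id,
#' description, then member gene symbols. Duplicate members within a term
#' are dropped.
#'
#' @param path Path to the GMT file.
#' @return Named list of unique member vectors; attribute `"names_desc"`
#'   maps term id to description.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  desc <- vapply(parts, `[`, character(1), 2L)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  attr(sets, "names_desc") <- stats::setNames(as.list(desc), ids)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets Named list of member vectors (optionally with a
#'   `"names_desc"` attribute of descriptions).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "names_desc")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(desc) && !is.null(desc[[id]])) desc[[id]] else id
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
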