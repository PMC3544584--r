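#' Coinertia analysis of paired mRNA and protein tables
#'
#' Finds paired axes of maximal covariance between two tables measured on
#' the same samples. With `X` and `Y` the column-centred samples x targets
#' log2 matrices and uniform row weight 1/n, the cross-covariance
#' `C = (1/n) t(X) %*% Y` is decomposed by SVD `C = U S t(V)`; the k-th
#' singular value is the co-inertia of axis k, and the first axis pair
#' maximises `cov(X u, Y v)` over unit vectors. Axis signs are fixed
#' deterministically (the largest-magnitude mRNA loading on each axis is
#' made positive, flipping the paired protein axis with it) so repeated
#' runs are identical.
#'
#' @param x,y Numeric matrices, samples x targets, identical dimnames
#'   ordering; n >= 3 samples.
#' @param k Number of axes to retain for scores (default 2).
#' @return Object of class `"cia"`: list with `lambda` (all singular
#'   values), `u`, `v` (target loadings, p x k), `mrna_scores`,
#'   `protein_scores` (loadings scaled by sqrt(lambda)), `sample_coscores_x`,
#'   `sample_coscores_y`, `rv`, `total_coinertia` (sum of squared singular
#'   values = squared Frobenius norm of `C`), and `k`.
#' @export
coinertia <- function(x, y, k = 2) {
  check_paired_tables(x, y)
  n <- nrow(x)
  k <- min(k, ncol(x), n - 1L)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  cc <- crossprod(xc, yc) / n
  sv <- svd(cc)
  # deterministic sign: largest |u| loading positive per axis
  for (j in seq_len(ncol(sv$u))) {
    i <- which.max(abs(sv$u[, j]))
    if (sv$u[i, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  lam <- sv$d
  dimnames(u) <- dimnames(v) <- list(colnames(x), paste0("axis", seq_len(k)))
  scl <- sqrt(lam[seq_len(k)])
  res <- list(
    lambda = lam, u = u, v = v,
    mrna_scores = sweep(u, 2L, scl, "*"),
    protein_scores = sweep(v, 2L, scl, "*"),
    sample_coscores_x = xc %*% u, sample_coscores_y = yc %*% v,
    rv = rv_coefficient(x, y),
    total_coinertia = sum(lam^2), k = k
  )
  class(res) <- "cia"
  res
}

#' RV coefficient of two paired tables
#'
#' Global matrix correlation in \[0, 1\]:
#' `RV = trace(Sxy Syx) / sqrt(trace(Sxx^2) trace(Syy^2))` with
#' `Sxy = (1/n) t(Xc) %*% Yc` etc. Equals 1 for `Y = cX` (c > 0) and is
#' near 0 for unrelated tables.
#'
#' @inheritParams coinertia
#' @return Scalar RV coefficient.
#' @export
rv_coefficient <- function(x, y) {
  check_paired_tables(x, y)
  n <- nrow(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sxy <- crossprod(xc, yc) / n
  sxx <- crossprod(xc) / n
  syy <- crossprod(yc) / n
  den <- sqrt(sum(sxx^2) * sum(syy^2))
  if (den == 0) stop("rv_coefficient: zero total inertia in a table")
  sum(sxy^2) / den  # trace(Sxy Syx) = sum(Sxy^2) since Syx = t(Sxy)
}

#' Normalised arrow coordinates for a coinertia score plot
#'
#' Each target is drawn as an arrow from its mRNA score (circular base) to
#' its protein score (arrowhead); the two score sets are independently
#' rescaled so their maximum Euclidean norm is 1, and the arrow length — the
#' base-to-head distance — summarises mRNA/protein divergence for that
#' target. Identical tables give all-zero lengths.
#'
#' @param res A `"cia"` object from [coinertia()].
#' @return Data frame sorted by descending `length`: `target`, base and head
#'   coordinates per axis (`base_1`, ..., `head_1`, ...), `length`.
#' @export
arrow_coordinates <- function(res) {
  stopifnot(inherits(res, "cia"))
  base <- unit_max_norm(res$mrna_scores)
  head <- unit_max_norm(res$protein_scores)
  len <- sqrt(rowSums((head - base)^2))
  out <- data.frame(target = rownames(base), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(base))) out[[paste0("base_", j)]] <- unname(base[, j])
  for (j in seq_len(ncol(head))) out[[paste0("head_", j)]] <- unname(head[, j])
  out$length <- unname(len)
  out <- out[order(-out$length, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

unit_max_norm <- function(m) {
  r <- sqrt(rowSums(m^2))
  mx <- max(r)
  if (mx > 0) m / mx else m
}

check_paired_tables <- function(x, y) {
  if (!is.matrix(x) || !is.matrix(y)) stop("paired tables must be matrices")
  if (!identical(dim(x), dim(y))) stop("paired tables must share shape n x p")
  if (nrow(x) < 3L) stop("paired tables need at least 3 samples")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("paired tables must be finite")
  }
  invisible(TRUE)
}
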