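#' Specific growth rate from two cell-density measurements
#'
#' Computes the exponential-phase specific growth rate
#' \eqn{\mu = (\ln d_2 - \ln d_1) / (t_2 - t_1)} in reciprocal hours from
#' viable cell densities at two time points.
#'
#' @param density1,density2 Viable cell densities (cells/mL) at `time1` and
#'   `time2`. Must be positive.
#' @param time1,time2 Sampling times in hours; `time2` must exceed `time1`.
#' @return Specific growth rate in h^-1. Positive iff `density2 > density1`.
#' @examples
#' growth_rate(2e5, 4e5, 0, 24)  # doubling in 24 h: log(2)/24
#' @export
growth_rate <- function(density1, density2, time1, time2) {
  if (any(!is.finite(c(density1, density2, time1, time2)))) {
    stop("growth_rate: all inputs must be finite")
  }
  if (any(density1 <= 0) || any(density2 <= 0)) {
    stop("growth_rate: cell densities must be positive")
  }
  if (any(time2 <= time1)) {
    stop("growth_rate: time2 must be greater than time1")
  }
  (log(density2) - log(density1)) / (time2 - time1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of raw p-values for multiple testing by the
#' Benjamini-Hochberg step-up procedure, preserving input order. `NA` entries
#' are kept `NA` and do not count toward the family size.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (q-values) in the original order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) stop("bh_adjust: empty p-value vector")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Welch two-sample test between fast and slow groups
#'
#' Two-sided Welch t-test p-value between two replicate vectors. Degenerate
#' inputs are resolved rather than erroring so batch loops stay total: if both
#' groups are constant with equal means the p-value is 1; if both are constant
#' with unequal means the statistic is computed with a small variance floor
#' (complete separation, p effectively 0).
#'
#' @param a,b Numeric vectors with at least 2 finite values each.
#' @return Raw two-sided p-value. Symmetric in `a` and `b`.
#' @export
two_group_test <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("two_group_test: each group needs at least 2 finite values")
  }
  va <- stats::var(a)
  vb <- stats::var(b)
  scale2 <- max(mean(a)^2, mean(b)^2, 1)
  degenerate <- (va + vb) <= .Machine$double.eps * 100 * scale2
  if (degenerate) {
    if (isTRUE(all.equal(mean(a), mean(b)))) return(1)
    # variance floor keeps complete separation finite and tiny
    floor_v <- 1e-8 * scale2
    tstat <- (mean(a) - mean(b)) / sqrt(floor_v / length(a) + floor_v / length(b))
    df <- length(a) + length(b) - 2
    return(2 * stats::pt(-abs(tstat), df))
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Pearson correlation coefficient
#'
#' Sample Pearson correlation between two equal-length vectors. Errors on
#' zero variance; callers that need a total function should trap this (the
#' growth-correlation stage flags such assays instead).
#'
#' @param x,y Numeric vectors, equal length >= 3, finite, nonzero variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("pearson: vectors must have equal length")
  if (length(x) < 3L) stop("pearson: need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("pearson: inputs must be finite")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("pearson: undefined correlation for zero-variance input")
  }
  stats::cor(x, y, method = "pearson")
}

#' Differential-expression call from fold change and significance
#'
#' Shared predicate used by all three expression layers: a feature is called
#' differentially expressed when its linear fold change is at least
#' `fc_min` in either direction (FC >= fc_min or FC <= 1/fc_min, inclusive)
#' and its significance value is below `alpha`.
#'
#' @param fc Linear fold change (fast over slow), positive.
#' @param sig Significance value compared against `alpha` (BH-adjusted q for
#'   miRNA/mRNA layers, raw p for the protein layer).
#' @param fc_min Fold-change threshold (default 1.2).
#' @param alpha Significance threshold (default 0.05).
#' @return Logical vector of DE calls; `NA` inputs give `FALSE`.
#' @export
flag_de <- function(fc, sig, fc_min = 1.2, alpha = 0.05) {
  ok <- !is.na(fc) & !is.na(sig)
  out <- logical(length(fc))
  out[ok] <- (fc[ok] >= fc_min | fc[ok] <= 1 / fc_min) & sig[ok] < alpha
  out
}
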