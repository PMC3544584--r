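#' Reference-gene normalisation of a Ct matrix
#'
#' Subtracts the reference assay's Ct from every other assay, per sample,
#' yielding delta-Ct values (lower delta-Ct = more template relative to the
#' reference). The reference row is removed from the result. Missing
#' ("undetermined") Ct values propagate as `NA`.
#'
#' @param ct Numeric matrix, assays x samples, rownames = assay ids,
#'   colnames = sample ids. Ct values in cycles; `NA` for undetermined wells.
#' @param reference_assay Row name of the endogenous control assay
#'   (default `"Mamm-U6"`); must have a finite Ct in every sample.
#' @return Delta-Ct matrix (assays x samples) without the reference row.
#' @export
normalize_ct <- function(ct, reference_assay = "Mamm-U6") {
  stopifnot(is.matrix(ct), !is.null(rownames(ct)), !is.null(colnames(ct)))
  if (!reference_assay %in% rownames(ct)) {
    stop("normalize_ct: reference assay '", reference_assay, "' not present")
  }
  ref <- ct[reference_assay, ]
  if (any(!is.finite(ref))) {
    stop("normalize_ct: reference assay must be finite in every sample")
  }
  dct <- sweep(ct, 2L, ref, "-")
  dct[setdiff(rownames(ct), reference_assay), , drop = FALSE]
}

#' Per-assay 2^-ddCt fold change between fast and slow groups
#'
#' delta-delta-Ct is the difference of group-mean delta-Ct values
#' (fast minus slow); the linear fold change is \eqn{2^{-\Delta\Delta Ct}},
#' so FC > 1 means higher expression in the fast group.
#'
#' @param dct Delta-Ct matrix (assays x samples).
#' @param groups Character vector named by sample id with values `"fast"` /
#'   `"slow"` (other labels ignored).
#' @return Data frame with columns `assay`, `ddct`, `fc`, `log2fc`, and
#'   `n_fast` / `n_slow` (finite observations used). Assays with an
#'   all-missing group get `NA` fold change.
#' @export
ddct_fold_change <- function(dct, groups) {
  grp <- match_groups(colnames(dct), groups)
  fast <- dct[, grp %in% "fast", drop = FALSE]
  slow <- dct[, grp %in% "slow", drop = FALSE]
  if (ncol(fast) == 0L || ncol(slow) == 0L) {
    stop("ddct_fold_change: both groups must be non-empty")
  }
  n_fast <- rowSums(is.finite(fast))
  n_slow <- rowSums(is.finite(slow))
  ddct <- rowMeans(fast, na.rm = TRUE) - rowMeans(slow, na.rm = TRUE)
  ddct[n_fast == 0L | n_slow == 0L] <- NA_real_
  data.frame(
    assay = rownames(dct), ddct = unname(ddct), fc = unname(2^(-ddct)),
    log2fc = unname(-ddct), n_fast = unname(n_fast), n_slow = unname(n_slow),
    stringsAsFactors = FALSE
  )
}

#' miRNA differential expression between growth groups
#'
#' Welch-tests each assay's delta-Ct values between the fast and slow groups,
#' adjusts across all tested assays by Benjamini-Hochberg, and calls a miRNA
#' differentially expressed when FC >= `fc_min` in either direction with
#' adjusted p < `alpha`. Assays with fewer than 2 finite values in either
#' group are excluded from testing (`tested = FALSE`, `NA` statistics).
#'
#' @inheritParams ddct_fold_change
#' @param fc_min Fold-change threshold (default 1.2).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return Data frame per assay: fold change fields of [ddct_fold_change()]
#'   plus `p`, `q`, `de`, `direction` (`"up"`/`"down"` in fast, `NA` if
#'   FC = 1 or untested) and `tested`.
#' @export
test_mirna_de <- function(dct, groups, fc_min = 1.2, alpha = 0.05) {
  res <- ddct_fold_change(dct, groups)
  grp <- match_groups(colnames(dct), groups)
  res$tested <- res$n_fast >= 2L & res$n_slow >= 2L
  res$p <- NA_real_
  for (i in which(res$tested)) {
    res$p[i] <- two_group_test(
      dct[i, grp %in% "fast"], dct[i, grp %in% "slow"]
    )
  }
  res$q <- NA_real_
  if (any(res$tested)) res$q[res$tested] <- bh_adjust(res$p[res$tested])
  res$de <- flag_de(res$fc, res$q, fc_min = fc_min, alpha = alpha)
  res$direction <- de_direction(res$log2fc)
  res
}

#' Growth-rate correlation per miRNA
#'
#' Pearson correlation of each assay with the per-sample growth rate, on
#' the expression scale (negative delta-Ct), so a positive coefficient means
#' expression rises with growth rate. The raw delta-Ct-scale coefficient
#' (its negative) is also reported. Assays with zero variance or fewer than
#' 3 paired finite observations are flagged `NA` and excluded downstream.
#'
#' @param dct Delta-Ct matrix (assays x samples).
#' @param growth Numeric growth rates (h^-1) named by sample id, covering
#'   every column of `dct`.
#' @return Data frame with columns `assay`, `pcc_expr`, `pcc_dct`, `n_used`.
#' @export
growth_correlation <- function(dct, growth) {
  if (!all(colnames(dct) %in% names(growth))) {
    stop("growth_correlation: growth rate missing for some samples")
  }
  g <- growth[colnames(dct)]
  pcc <- vapply(seq_len(nrow(dct)), function(i) {
    expr <- -dct[i, ]
    ok <- is.finite(expr) & is.finite(g)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::var(expr[ok]) == 0 || stats::var(g[ok]) == 0) return(NA_real_)
    pearson(expr[ok], g[ok])
  }, numeric(1))
  n_used <- vapply(seq_len(nrow(dct)), function(i) {
    sum(is.finite(dct[i, ]) & is.finite(g))
  }, integer(1))
  data.frame(
    assay = rownames(dct), pcc_expr = pcc, pcc_dct = -pcc, n_used = n_used,
    stringsAsFactors = FALSE
  )
}

#' Prioritise miRNAs by combined DE and growth-correlation evidence
#'
#' A miRNA is high priority when it is differentially expressed between the
#' growth groups and its expression-scale growth correlation satisfies
#' |PCC| >= `pcc_min` (inclusive). The priority set is partitioned into
#' up-with-growth and down-with-growth by the sign of the log2 fold change.
#'
#' @param de Output of [test_mirna_de()].
#' @param pcc Output of [growth_correlation()] over the same assays.
#' @param pcc_min Absolute correlation threshold (default 0.4).
#' @return `de` with `pcc_expr`, `pcc_dct` and a logical `priority` column
#'   merged in; attribute `"partition"` holds the up/down assay id split.
#' @export
prioritize <- function(de, pcc, pcc_min = 0.4) {
  if (!setequal(de$assay, pcc$assay)) {
    stop("prioritize: DE and correlation tables cover different assays")
  }
  out <- merge(de, pcc[, c("assay", "pcc_expr", "pcc_dct")],
               by = "assay", sort = FALSE)
  out <- out[match(de$assay, out$assay), ]
  rownames(out) <- NULL
  out$priority <- out$de & !is.na(out$pcc_expr) & abs(out$pcc_expr) >= pcc_min
  attr(out, "partition") <- list(
    up = out$assay[out$priority & out$direction == "up"],
    down = out$assay[out$priority & out$direction == "down"]
  )
  out
}

# fast/slow label per column id; NA for unlabelled samples
match_groups <- function(sample_ids, groups) {
  if (is.null(names(groups))) stop("groups must be named by sample id")
  g <- unname(groups[sample_ids])
  g[!g %in% c("fast", "slow")] <- NA_character_
  g
}

de_direction <- function(log2fc) {
  ifelse(is.na(log2fc) | log2fc == 0, NA_character_,
         ifelse(log2fc > 0, "up", "down"))
}
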