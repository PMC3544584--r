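#' Peptide feature filtering
#'
#' Retains peptide features that satisfy all four quality criteria used
#' before protein rollup: feature ANOVA p < `alpha` across clone groups,
#' charge state within `charge_range` (inclusive), isotope count strictly
#' greater than `min_isotopes_exclusive`, and ion score at least
#' `min_ion_score` (inclusive). When the `anova_p` column is missing or
#' `NA`, it is computed as a one-way ANOVA of that feature's abundances
#' across groups.
#'
#' @param peptides Data frame with columns `peptide`, `protein`, `charge`,
#'   `isotopes`, `ion_score`, `unique`, optionally `anova_p`, and one
#'   abundance column per run (names in `runs`).
#' @param runs Character vector of abundance column names.
#' @param run_groups Character vector named by run id with values
#'   `"fast"`/`"slow"`; needed only when `anova_p` must be computed.
#' @param alpha ANOVA p-value threshold (default 0.05, strict `<`).
#' @param charge_range Inclusive charge window, default `c(1, 3)`.
#' @param min_isotopes_exclusive Isotope count must exceed this (default 3).
#' @param min_ion_score Minimum ion score, inclusive (default 30).
#' @return List with `retained` (filtered data frame, `anova_p` filled in)
#'   and `rejected` (data frame `peptide`, `reason` naming the first failed
#'   criterion).
#' @export
filter_peptides <- function(peptides, runs, run_groups = NULL, alpha = 0.05,
                            charge_range = c(1, 3),
                            min_isotopes_exclusive = 3, min_ion_score = 30) {
  needed <- c("peptide", "protein", "charge", "isotopes", "ion_score", "unique")
  stopifnot(all(needed %in% names(peptides)), all(runs %in% names(peptides)))
  p <- peptides
  if (is.null(p$anova_p)) p$anova_p <- NA_real_
  miss <- which(is.na(p$anova_p))
  if (length(miss) > 0L) {
    if (is.null(run_groups)) {
      stop("filter_peptides: anova_p missing and no run_groups to compute it")
    }
    for (i in miss) {
      p$anova_p[i] <- feature_anova_p(as.numeric(p[i, runs]),
                                      match_groups(runs, run_groups))
    }
  }
  pass_p <- !is.na(p$anova_p) & p$anova_p < alpha
  pass_charge <- p$charge >= charge_range[1] & p$charge <= charge_range[2]
  pass_iso <- p$isotopes > min_isotopes_exclusive
  pass_score <- p$ion_score >= min_ion_score
  keep <- pass_p & pass_charge & pass_iso & pass_score
  reason <- rep(NA_character_, nrow(p))
  reason[!pass_score] <- "ion_score"
  reason[!pass_iso] <- "isotopes"
  reason[!pass_charge] <- "charge"
  reason[!pass_p] <- "anova_p"
  list(
    retained = p[keep, , drop = FALSE],
    rejected = data.frame(peptide = p$peptide[!keep],
                          reason = reason[!keep], stringsAsFactors = FALSE)
  )
}

# one-way ANOVA p of a feature's abundances across groups; degenerate
# within-group-constant cases resolved as complete separation (0) or
# no signal (1)
feature_anova_p <- function(abundance, group) {
  ok <- is.finite(abundance) & !is.na(group)
  y <- abundance[ok]
  g <- factor(group[ok])
  if (nlevels(g) < 2L || length(y) < 3L) return(NA_real_)
  ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  if (ss_within <= .Machine$double.eps * 100 * max(ss_between, 1)) {
    return(if (ss_between <= .Machine$double.eps * 100) 1 else 0)
  }
  stats::anova(stats::lm(y ~ g))[["Pr(>F)"]][1]
}

#' Roll peptides up to a protein abundance matrix
#'
#' Protein abundance per run is the sum of abundances of retained peptides
#' that map uniquely to that protein; shared (non-unique) peptides contribute
#' nothing. Proteins with no retained unique peptide are absent from the
#' matrix.
#'
#' @param retained Filtered peptide data frame (see [filter_peptides()]).
#' @param runs Character vector of abundance column names.
#' @return List with `abundance` (protein x run matrix) and `peptide_count`
#'   (named integer vector of retained unique peptides per protein).
#' @export
rollup <- function(retained, runs) {
  uq <- retained[as.logical(retained$unique), , drop = FALSE]
  if (nrow(uq) == 0L) {
    return(list(abundance = matrix(numeric(), 0L, length(runs),
                                   dimnames = list(NULL, runs)),
                peptide_count = integer()))
  }
  proteins <- sort(unique(uq$protein))
  ab <- matrix(0, length(proteins), length(runs),
               dimnames = list(proteins, runs))
  for (r in runs) {
    ab[, r] <- tapply(uq[[r]], factor(uq$protein, levels = proteins),
                      sum)[proteins]
  }
  list(abundance = ab,
       peptide_count = vapply(proteins, function(pr) sum(uq$protein == pr),
                              integer(1)))
}

#' Aggregate protein runs to clone-level abundances
#'
#' Averages log-scale abundances of replicate runs belonging to the same
#' clone, returning a protein x clone log2 matrix (pseudocount 1) so that
#' clones — the biological unit — enter the group test once each.
#'
#' @param abundance Protein x run abundance matrix (linear scale).
#' @param run_to_clone Character vector named by run id giving the clone id.
#' @param pseudocount Added before log2 (default 1).
#' @return Protein x clone matrix of mean log2 abundances.
#' @export
aggregate_runs <- function(abundance, run_to_clone, pseudocount = 1) {
  stopifnot(all(colnames(abundance) %in% names(run_to_clone)))
  clone <- run_to_clone[colnames(abundance)]
  lg <- log2(abundance + pseudocount)
  clones <- unique(unname(clone))
  if (nrow(abundance) == 0L) {
    return(matrix(numeric(), 0L, length(clones),
                  dimnames = list(NULL, clones)))
  }
  out <- vapply(clones, function(cl) {
    rowMeans(lg[, clone == cl, drop = FALSE])
  }, numeric(nrow(abundance)))
  out <- matrix(out, nrow = nrow(abundance),
                dimnames = list(rownames(abundance), clones))
  out
}

#' Protein differential expression between growth groups
#'
#' Tests clone-level log2 protein abundances between fast and slow groups
#' (Welch). A protein is DE when it has at least `min_peptides` retained
#' unique peptides, FC >= `fc_min` in either direction, and raw p < `alpha`
#' — the raw p-value is the protein-layer criterion; the BH-adjusted value
#' is reported alongside for transparency.
#'
#' @param log2_abundance Protein x clone matrix of log2 abundances.
#' @param groups Character vector named by clone id, values `"fast"`/`"slow"`.
#' @param peptide_count Named integer vector of unique-peptide counts.
#' @param min_peptides Minimum peptides matched per protein (default 2).
#' @param fc_min Fold-change threshold (default 1.2).
#' @param alpha Raw-p significance threshold (default 0.05).
#' @return Data frame per protein: `protein`, `n_peptides`, `log2fc`, `fc`,
#'   `p`, `q`, `de`, `direction`, `excluded_few_peptides`.
#' @export
test_protein_de <- function(log2_abundance, groups, peptide_count,
                            min_peptides = 2, fc_min = 1.2, alpha = 0.05) {
  grp <- match_groups(colnames(log2_abundance), groups)
  fast <- log2_abundance[, grp %in% "fast", drop = FALSE]
  slow <- log2_abundance[, grp %in% "slow", drop = FALSE]
  if (ncol(fast) < 2L || ncol(slow) < 2L) {
    stop("test_protein_de: need at least 2 clones per group")
  }
  prot <- rownames(log2_abundance)
  npep <- peptide_count[prot]
  log2fc <- rowMeans(fast) - rowMeans(slow)
  p <- vapply(seq_along(prot), function(i) {
    two_group_test(fast[i, ], slow[i, ])
  }, numeric(1))
  q <- bh_adjust(p)
  enough <- !is.na(npep) & npep >= min_peptides
  de <- flag_de(2^log2fc, p, fc_min, alpha) & enough
  data.frame(
    protein = prot, n_peptides = as.integer(npep),
    log2fc = unname(log2fc), fc = unname(2^log2fc), p = p, q = q,
    de = unname(de), direction = de_direction(unname(log2fc)),
    excluded_few_peptides = unname(!enough), stringsAsFactors = FALSE
  )
}

#' Flag outlying samples on a log2 protein matrix by PCA
#'
#' Optional quality-control pre-step: principal components analysis of the
#' samples; a sample is flagged when its distance from the centroid in the
#' PC1-PC2 plane exceeds `k` times the median absolute deviation of those
#' distances. Disabled by default in the pipeline; flagged ids are logged,
#' removal is the caller's decision.
#'
#' @param log2_abundance Protein x sample log2 matrix.
#' @param k MAD multiplier (default 4).
#' @return Character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_samples <- function(log2_abundance, k = 4) {
  pc <- stats::prcomp(t(log2_abundance), center = TRUE, scale. = FALSE)
  sc <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  d <- sqrt(rowSums(sweep(sc, 2L, colMeans(sc), "-")^2))
  cut <- stats::median(d) + k * stats::mad(d)
  colnames(log2_abundance)[d > cut]
}
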