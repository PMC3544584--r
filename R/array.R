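#' Detection-threshold filter for microarray probesets
#'
#' A probeset is detected when its log2 fluorescence reaches the detection
#' threshold (default log2(100)) in at least one sample; the comparison is
#' inclusive. The partition into detected and undetected is exhaustive.
#'
#' @param expr Numeric matrix of log2 intensities, probesets x samples.
#' @param threshold Log2-intensity detection threshold (default `log2(100)`).
#' @return List with `detected` (sub-matrix) and `undetected_ids`.
#' @export
detection_filter <- function(expr, threshold = log2(100)) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  hit <- apply(expr, 1L, max, na.rm = TRUE) >= threshold
  list(
    detected = expr[hit, , drop = FALSE],
    undetected_ids = rownames(expr)[!hit]
  )
}

#' Probeset differential expression between growth groups
#'
#' For each (detection-filtered) probeset, the fold change is the ratio of
#' group geometric means, `2^(mean log2 fast - mean log2 slow)`; the p-value
#' is a Welch test on the per-sample log2 intensities; adjustment is
#' Benjamini-Hochberg across all tested probesets. A probeset is DE when
#' FC >= `fc_min` in either direction with adjusted p < `alpha`.
#'
#' @param expr Log2 intensity matrix (detected probesets x samples).
#' @param groups Character vector named by sample id, values `"fast"`/`"slow"`.
#' @param fc_min Fold-change threshold (default 1.2).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @return Data frame per probeset: `probeset`, `log2fc`, `fc`, `mean_expr`
#'   (across all samples), `p`, `q`, `de`, `direction`.
#' @export
test_mrna_de <- function(expr, groups, fc_min = 1.2, alpha = 0.05) {
  grp <- match_groups(colnames(expr), groups)
  fast <- expr[, grp %in% "fast", drop = FALSE]
  slow <- expr[, grp %in% "slow", drop = FALSE]
  if (ncol(fast) < 2L || ncol(slow) < 2L) {
    stop("test_mrna_de: need at least 2 samples per group")
  }
  if (nrow(expr) == 0L) {
    return(data.frame(probeset = character(), log2fc = numeric(),
                      fc = numeric(), mean_expr = numeric(), p = numeric(),
                      q = numeric(), de = logical(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  log2fc <- rowMeans(fast) - rowMeans(slow)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    two_group_test(fast[i, ], slow[i, ])
  }, numeric(1))
  q <- bh_adjust(p)
  data.frame(
    probeset = rownames(expr), log2fc = unname(log2fc),
    fc = unname(2^log2fc), mean_expr = unname(rowMeans(expr)),
    p = p, q = q, de = flag_de(2^log2fc, q, fc_min, alpha),
    direction = de_direction(unname(log2fc)),
    stringsAsFactors = FALSE
  )
}

#' Collapse DE probesets to non-redundant annotated genes
#'
#' Keeps only differentially expressed probesets with a gene annotation and
#' collapses genes hit by several DE probesets to a single record, keeping
#' the probeset with the highest mean expression as the representative
#' (ties broken by lexicographically smallest probeset id). Genes whose DE
#' probesets disagree in direction are flagged.
#'
#' @param de Output of [test_mrna_de()].
#' @param annotation Data frame with columns `probeset`, `gene`; `NA` or
#'   empty gene means unannotated.
#' @return Gene-level data frame: `gene`, `probeset` (representative),
#'   `log2fc`, `fc`, `mean_expr`, `p`, `q`, `direction`, `n_probesets`,
#'   `direction_conflict`.
#' @export
annotate_and_dedupe <- function(de, annotation) {
  stopifnot(all(c("probeset", "gene") %in% names(annotation)))
  hits <- de[de$de, , drop = FALSE]
  hits$gene <- annotation$gene[match(hits$probeset, annotation$probeset)]
  hits <- hits[!is.na(hits$gene) & nzchar(hits$gene), , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(
      gene = character(), probeset = character(), log2fc = numeric(),
      fc = numeric(), mean_expr = numeric(), p = numeric(), q = numeric(),
      direction = character(), n_probesets = integer(),
      direction_conflict = logical(), stringsAsFactors = FALSE
    ))
  }
  # deterministic representative: highest mean expression, then smallest id
  hits <- hits[order(hits$gene, -hits$mean_expr, hits$probeset), , drop = FALSE]
  n_ps <- table(hits$gene)
  conflict <- tapply(hits$direction, hits$gene,
                     function(d) length(unique(d)) > 1L)
  rep <- hits[!duplicated(hits$gene), , drop = FALSE]
  rep$n_probesets <- as.integer(n_ps[rep$gene])
  rep$direction_conflict <- as.logical(conflict[rep$gene])
  rownames(rep) <- NULL
  rep[, c("gene", "probeset", "log2fc", "fc", "mean_expr", "p", "q",
          "direction", "n_probesets", "direction_conflict")]
}
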