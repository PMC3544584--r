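#' Pipeline configuration
#'
#' Collects every threshold used across the stages in one place so no stage
#' carries a literal: fold-change and significance cutoffs, the growth-rate
#' correlation filter, the array detection threshold, the minimum peptide
#' count, and the fast/slow growth cutoffs.
#'
#' @param fc_min Fold-change threshold, all layers (default 1.2).
#' @param alpha Significance threshold: BH-adjusted for miRNA/mRNA, raw for
#'   protein (default 0.05).
#' @param pcc_min Absolute growth-correlation threshold (default 0.4).
#' @param detection_threshold Array log2 detection threshold
#'   (default `log2(100)`).
#' @param min_peptides Minimum unique peptides per protein (default 2).
#' @param fast_cutoff,slow_cutoff Growth-rate group cutoffs in h^-1
#'   (defaults 0.025 / 0.023, inclusive on both sides).
#' @param reference_assay qPCR reference assay id (default `"Mamm-U6"`).
#' @param ease Use the EASE-discounted enrichment variant (default `FALSE`).
#' @param remove_outlier_runs Apply the PCA/MAD proteomic sample flagging
#'   pre-step and drop flagged clones (default `FALSE`).
#' @param outlier_k MAD multiplier for the outlier rule (default 4).
#' @param cia_axes Number of coinertia axes (default 2).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(fc_min = 1.2, alpha = 0.05, pcc_min = 0.4,
                            detection_threshold = log2(100),
                            min_peptides = 2, fast_cutoff = 0.025,
                            slow_cutoff = 0.023,
                            reference_assay = "Mamm-U6", ease = FALSE,
                            remove_outlier_runs = FALSE, outlier_k = 4,
                            cia_axes = 2) {
  cfg <- as.list(environment())
  if (any(c(fc_min, alpha, pcc_min, detection_threshold, min_peptides) <= 0)) {
    stop("pipeline_config: thresholds must be positive")
  }
  if (slow_cutoff >= fast_cutoff) {
    stop("pipeline_config: fast cutoff must exceed slow cutoff")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Assign clones to fast and slow growth groups
#'
#' Fast iff growth rate >= `fast_cutoff`; slow iff rate <= `slow_cutoff`
#' (both inclusive); rates falling strictly between the cutoffs are labelled
#' `"unassigned"` and excluded from group tests.
#'
#' @param samples Data frame with columns `clone`, `growth_rate`.
#' @param fast_cutoff,slow_cutoff Group cutoffs in h^-1.
#' @return `samples` with a `group` column added.
#' @export
assign_groups <- function(samples, fast_cutoff = 0.025, slow_cutoff = 0.023) {
  stopifnot(all(c("clone", "growth_rate") %in% names(samples)))
  if (slow_cutoff >= fast_cutoff) {
    stop("assign_groups: fast cutoff must exceed slow cutoff")
  }
  samples$group <- ifelse(samples$growth_rate >= fast_cutoff, "fast",
                          ifelse(samples$growth_rate <= slow_cutoff, "slow",
                                 "unassigned"))
  samples
}

#' Run the integrated miRNA/mRNA/protein pipeline end to end
#'
#' Executes the four analysis stages in order on an input bundle:
#' per-layer differential expression (miRNA delta-delta-Ct, detection-gated
#' microarray, peptide-rollup proteomics), overrepresentation analysis of
#' the DE lists, protein-to-probeset mapping with Group A/B candidate
#' classification, anti-correlated conserved-target overlap, and coinertia
#' analysis of the Group-A-linked mRNA/protein profiles. Fully
#' deterministic given the bundle and configuration.
#'
#' @param bundle A `sim_bundle` (from [simulate_study()] or
#'   [read_bundle()]); any list with the same components works for real
#'   data.
#' @param config A [pipeline_config()] (defaults used when omitted).
#' @return List with per-stage tables (`samples`, `mirna`, `mrna_probeset`,
#'   `mrna_gene`, `protein`, `enrichment_protein`, `enrichment_mrna`,
#'   `map`, `candidates`, `edges`, `cia`, `arrows`, `report`).
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  samples <- assign_groups(bundle$samples, config$fast_cutoff,
                           config$slow_cutoff)
  groups <- stats::setNames(samples$group, samples$clone)
  growth <- stats::setNames(samples$growth_rate, samples$clone)

  # stage 1a: miRNA
  dct <- normalize_ct(bundle$ct, config$reference_assay)
  mirna_de <- test_mirna_de(dct, groups, config$fc_min, config$alpha)
  pcc <- growth_correlation(dct, growth)
  mirna <- prioritize(mirna_de, pcc, config$pcc_min)

  # stage 1b: mRNA
  det <- detection_filter(bundle$expr, config$detection_threshold)
  mrna_probeset <- test_mrna_de(det$detected, groups, config$fc_min,
                                config$alpha)
  mrna_gene <- annotate_and_dedupe(mrna_probeset, bundle$annotation)

  # stage 1c: protein
  run_to_clone <- stats::setNames(bundle$run_map$clone, bundle$run_map$run)
  run_groups <- stats::setNames(groups[run_to_clone[bundle$runs]],
                                bundle$runs)
  filt <- filter_peptides(bundle$peptides, bundle$runs, run_groups,
                          alpha = config$alpha)
  rl <- rollup(filt$retained, bundle$runs)
  prot_log2 <- aggregate_runs(rl$abundance, run_to_clone)
  dropped_clones <- character()
  if (config$remove_outlier_runs && ncol(prot_log2) > 3L) {
    dropped_clones <- flag_outlier_samples(prot_log2, config$outlier_k)
    prot_log2 <- prot_log2[, !colnames(prot_log2) %in% dropped_clones,
                           drop = FALSE]
  }
  protein <- test_protein_de(prot_log2, groups, rl$peptide_count,
                             config$min_peptides, config$fc_min,
                             config$alpha)

  # stage 2: enrichment of the DE lists
  universe <- unique(bundle$annotation$gene[
    !is.na(bundle$annotation$gene) & nzchar(bundle$annotation$gene)])
  enrich_safe <- function(hits) {
    hits <- intersect(hits, universe)
    if (length(hits) == 0L) return(NULL)
    enrich(hits, bundle$gmt, universe, ease = config$ease)
  }
  enrichment_protein <- enrich_safe(protein$protein[protein$de])
  enrichment_mrna <- enrich_safe(mrna_gene$gene)

  # stage 3: mapping and Group A/B classification
  map <- map_proteins(protein, bundle$annotation, bundle$expr)
  candidates <- classify(protein, mrna_gene, rownames(det$detected), map)

  # stage 4: anti-correlated conserved-target overlap
  edges <- overlap(candidates, mirna, bundle$predictions)

  # coinertia on the Group-A-linked targets
  cia_res <- NULL
  arrows <- NULL
  a_linked <- sort(unique(edges$candidate[edges$group == "A"]))
  a_linked <- a_linked[a_linked %in% rownames(prot_log2)]
  reps <- map$representative[match(a_linked, map$protein)]
  ok <- !is.na(reps) & reps %in% rownames(bundle$expr)
  a_linked <- a_linked[ok]
  reps <- reps[ok]
  common <- intersect(colnames(bundle$expr), colnames(prot_log2))
  if (length(a_linked) >= 1L && length(common) >= 3L) {
    x <- t(bundle$expr[reps, common, drop = FALSE])
    colnames(x) <- a_linked
    y <- t(prot_log2[a_linked, common, drop = FALSE])
    # a degenerate table (zero inertia, e.g. exactly constant mRNA) has no
    # defined co-structure; the stage is skipped rather than aborting the run
    nonzero <- function(m) sum(scale(m, scale = FALSE)^2) > 0
    if (nonzero(x) && nonzero(y)) {
      cia_res <- coinertia(x, y, config$cia_axes)
      arrows <- arrow_coordinates(cia_res)
    }
  }

  smry <- attr(edges, "summary")
  report <- data.frame(
    metric = c("n_samples", "n_fast", "n_slow", "n_unassigned",
               "n_mirna_assays", "n_mirna_de", "n_mirna_priority",
               "n_mirna_priority_up", "n_mirna_priority_down",
               "n_probesets", "n_detected", "n_mrna_de_probesets",
               "n_mrna_de_genes", "n_peptides_in", "n_peptides_retained",
               "n_proteins_quantified", "n_protein_de", "n_dropped_clones",
               "n_group_a", "n_group_b", "n_edges",
               "frac_group_a_with_edge", "frac_group_b_with_edge",
               "rv_coefficient"),
    value = c(nrow(samples), sum(samples$group == "fast"),
              sum(samples$group == "slow"),
              sum(samples$group == "unassigned"),
              nrow(dct), sum(mirna$de), sum(mirna$priority),
              sum(mirna$priority & mirna$direction == "up"),
              sum(mirna$priority & mirna$direction == "down"),
              nrow(bundle$expr), nrow(det$detected),
              sum(mrna_probeset$de), nrow(mrna_gene),
              nrow(bundle$peptides), nrow(filt$retained),
              nrow(prot_log2), sum(protein$de), length(dropped_clones),
              sum(candidates$group == "A"), sum(candidates$group == "B"),
              nrow(edges),
              smry$fraction_with_edge[smry$group == "A"],
              smry$fraction_with_edge[smry$group == "B"],
              if (is.null(cia_res)) NA_real_ else cia_res$rv),
    stringsAsFactors = FALSE
  )

  list(samples = samples, mirna = mirna, mrna_probeset = mrna_probeset,
       mrna_gene = mrna_gene, protein = protein,
       enrichment_protein = enrichment_protein,
       enrichment_mrna = enrichment_mrna, map = map,
       candidates = candidates, edges = edges, cia = cia_res,
       arrows = arrows, dropped_clones = dropped_clones, report = report)
}

#' Run the pipeline and write every intermediate to a directory
#'
#' Thin wrapper over [run_pipeline()] that serialises all stage outputs as
#' TSV files (plus the network export). Rerunning with the same bundle and
#' configuration produces byte-identical files.
#'
#' @inheritParams run_pipeline
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the [run_pipeline()] result.
#' @export
run_all <- function(bundle, outdir, config = pipeline_config()) {
  res <- run_pipeline(bundle, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$samples, file.path(outdir, "samples_groups.tsv"))
  mir <- res$mirna
  attr(mir, "partition") <- NULL
  write_tsv(mir, file.path(outdir, "mirna_de.tsv"))
  write_tsv(res$mrna_probeset, file.path(outdir, "mrna_de_probesets.tsv"))
  write_tsv(res$mrna_gene, file.path(outdir, "mrna_de_genes.tsv"))
  write_tsv(res$protein, file.path(outdir, "protein_de.tsv"))
  if (!is.null(res$enrichment_protein)) {
    write_tsv(res$enrichment_protein,
              file.path(outdir, "enrichment_protein.tsv"))
  }
  if (!is.null(res$enrichment_mrna)) {
    write_tsv(res$enrichment_mrna, file.path(outdir, "enrichment_mrna.tsv"))
  }
  write_tsv(res$map, file.path(outdir, "protein_probeset_map.tsv"))
  write_tsv(res$candidates, file.path(outdir, "candidate_groups.tsv"))
  export_network(res$edges, file.path(outdir, "network"))
  smry <- attr(res$edges, "summary")
  write_tsv(smry, file.path(outdir, "overlap_summary.tsv"))
  if (!is.null(res$arrows)) {
    write_tsv(res$arrows, file.path(outdir, "cia_arrows.tsv"))
    cia_tab <- data.frame(
      axis = seq_along(res$cia$lambda), lambda = res$cia$lambda,
      pct_coinertia = 100 * res$cia$lambda^2 / res$cia$total_coinertia,
      rv = res$cia$rv, stringsAsFactors = FALSE
    )
    write_tsv(cia_tab, file.path(outdir, "cia_summary.tsv"))
  }
  write_tsv(res$report, file.path(outdir, "report.tsv"))
  invisible(res)
}
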