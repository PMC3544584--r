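#' Configuration for a synthetic growth-rate multi-omics study
#'
#' Defines the study conditions the generator emulates: a panel of clonal
#' cell lines spanning a continuous growth-rate range, split into fast and
#' slow groups, profiled in parallel at the miRNA (qPCR Ct), mRNA (log2
#' microarray) and protein (peptide-level label-free) layers, with planted
#' miRNA regulators whose expression tracks growth rate and planted targets
#' showing the translational-repression signature (protein change without
#' mRNA change) or mixed-evidence patterns.
#'
#' Defaults mirror the emulated design: 30 clones over 0.011-0.044 h^-1,
#' 15 fast (>= 0.025) vs 15 slow (<= 0.023), 3 proteomic replicate runs per
#' clone; a Ct slope of 40 cycles per h^-1 (about a 1.6-fold planted miRNA
#' fold change between the groups) and 0.5 log2-unit planted mRNA/protein
#' effects; Gaussian noise on Ct and log2 intensities and log-normal
#' peptide abundances.
#'
#' @param n_fast,n_slow Clones per growth group (defaults 15/15).
#' @param growth_range Growth-rate range in h^-1 (default `c(0.011, 0.044)`).
#' @param fast_cutoff,slow_cutoff Group thresholds (defaults 0.025 / 0.023).
#' @param reps_proteomics Proteomic replicate runs per clone (default 3).
#' @param n_mirna_up,n_mirna_down,n_mirna_null Planted miRNA counts
#'   (defaults 10 / 6 / 44).
#' @param n_group_a Planted translational-repression targets (default 12).
#' @param n_group_b Planted mixed-evidence targets, cycled over the three
#'   patterns: probeset absent/undetected, mRNA-only, dual DE (default 9).
#' @param n_null_genes Unregulated genes (default 120).
#' @param n_null_proteins How many null genes also carry a protein
#'   (default 40).
#' @param n_unannotated Unannotated flat probesets (default 15).
#' @param ct_slope Ct cycles per unit growth rate for planted miRNAs
#'   (default 40).
#' @param mrna_log2_effect,protein_log2_effect Planted log2 group effects
#'   (defaults 0.5 / 0.5).
#' @param sd_ct,sd_array,sd_protein Noise standard deviations: Ct cycles,
#'   log2 array intensity, log2 run-level protein abundance
#'   (defaults 0.2 / 0.2 / 0.15).
#' @param decoy_rate Decoy prediction rows per planted edge (default 2).
#' @param reference_assay Reference assay id (default `"Mamm-U6"`).
#' @param seed Mandatory RNG seed; the same seed yields a byte-identical
#'   bundle.
#' @return A `sim_config` list (validated).
#' @export
sim_config <- function(n_fast = 15, n_slow = 15,
                       growth_range = c(0.011, 0.044),
                       fast_cutoff = 0.025, slow_cutoff = 0.023,
                       reps_proteomics = 3,
                       n_mirna_up = 10, n_mirna_down = 6, n_mirna_null = 44,
                       n_group_a = 12, n_group_b = 9, n_null_genes = 120,
                       n_null_proteins = 40, n_unannotated = 15,
                       ct_slope = 40,
                       mrna_log2_effect = 0.5, protein_log2_effect = 0.5,
                       sd_ct = 0.2, sd_array = 0.2, sd_protein = 0.15,
                       decoy_rate = 2, reference_assay = "Mamm-U6",
                       seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  cfg <- as.list(environment())
  counts <- c(n_fast, n_slow, reps_proteomics, n_mirna_up, n_mirna_down,
              n_mirna_null, n_group_a, n_group_b, n_null_genes,
              n_null_proteins, n_unannotated)
  if (any(counts < 0)) stop("sim_config: counts must be non-negative")
  if (n_fast + n_slow < 4) stop("sim_config: need at least 4 clones")
  if (slow_cutoff >= fast_cutoff) {
    stop("sim_config: slow_cutoff must be below fast_cutoff")
  }
  if (fast_cutoff > growth_range[2] || slow_cutoff < growth_range[1]) {
    stop("sim_config: cutoffs must lie inside the growth range")
  }
  if (n_group_a + n_group_b > 0 && n_mirna_up + n_mirna_down == 0) {
    stop("sim_config: planted targets require at least one planted miRNA")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a complete multi-omics study with planted ground truth
#'
#' Generates the full input bundle for the pipeline — sample metadata, miRNA
#' Ct matrix with reference assay, log2 microarray matrix with probeset
#' annotation, run-level peptide quantification table, conserved
#' target-prediction table with decoys, a GMT term collection, and a truth
#' ledger of planted miRNA classes, target classes and regulatory edges.
#'
#' Planted regulator miRNAs have Ct values that fall (up class) or rise
#' (down class) linearly with growth rate; each planted target's mRNA
#' and/or protein signal is coupled to its regulator's realised expression
#' (not the group label), calibrated so the fast-vs-slow group effect equals
#' the configured log2 effect — so anti-correlation filtering is genuinely
#' exercised. Target patterns: translational repression (flat mRNA, coupled
#' protein), probeset-absent or sub-detection protein DE, mRNA-only DE, and
#' concordant dual DE.
#'
#' @param cfg A [sim_config()] object.
#' @return A `sim_bundle` list: `samples`, `run_map`, `ct`, `expr`,
#'   `annotation`, `peptides`, `runs`, `predictions`, `gmt`, `truth`
#'   (`mirnas`, `targets`, `edges`), `config`.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  mid <- mean(cfg$growth_range)

  # --- samples -------------------------------------------------------------
  n <- cfg$n_fast + cfg$n_slow
  rates <- c(stats::runif(cfg$n_fast, cfg$fast_cutoff, cfg$growth_range[2]),
             stats::runif(cfg$n_slow, cfg$growth_range[1], cfg$slow_cutoff))
  ord <- sample.int(n)
  clones <- sprintf("CL%02d", seq_len(n))
  samples <- data.frame(clone = clones, growth_rate = rates[ord],
                        stringsAsFactors = FALSE)
  growth <- stats::setNames(samples$growth_rate, samples$clone)
  true_grp <- ifelse(growth >= cfg$fast_cutoff, "fast", "slow")

  # --- miRNA Ct matrix -----------------------------------------------------
  mir_up <- sprintf("sim-miR-u%02d", seq_len(cfg$n_mirna_up))
  mir_down <- sprintf("sim-miR-d%02d", seq_len(cfg$n_mirna_down))
  mir_null <- sprintf("sim-miR-n%02d", seq_len(cfg$n_mirna_null))
  assays <- c(mir_up, mir_down, mir_null)
  base_ct <- stats::runif(length(assays), 24, 30)
  slope <- c(rep(-cfg$ct_slope, cfg$n_mirna_up),
             rep(cfg$ct_slope, cfg$n_mirna_down),
             rep(0, cfg$n_mirna_null))
  ct <- matrix(NA_real_, length(assays) + 1L, n,
               dimnames = list(c(assays, cfg$reference_assay), clones))
  for (i in seq_along(assays)) {
    ct[i, ] <- base_ct[i] + slope[i] * (growth - mid) +
      stats::rnorm(n, 0, cfg$sd_ct)
  }
  ct[cfg$reference_assay, ] <- 20 + stats::rnorm(n, 0, cfg$sd_ct / 4)
  # regulator expression on the scale the pipeline sees: -dCt
  mir_expr <- sweep(-ct[assays, , drop = FALSE], 2L,
                    -ct[cfg$reference_assay, ], "-")

  # --- genes and planted classes -------------------------------------------
  n_genes <- cfg$n_group_a + cfg$n_group_b + cfg$n_null_genes
  genes <- sprintf("GENE%04d", seq_len(n_genes))
  class_vec <- c(
    rep("A", cfg$n_group_a),
    if (cfg$n_group_b > 0)
      c("B_absent", "B_mrna_only", "B_dual")[
        (seq_len(cfg$n_group_b) - 1L) %% 3L + 1L]
    else character(),
    rep("null", cfg$n_null_genes)
  )
  regulators <- rep(NA_character_, n_genes)
  planted <- which(class_vec != "null")
  pool <- c(mir_up, mir_down)
  if (length(planted) > 0) {
    regulators[planted] <- pool[(seq_along(planted) - 1L) %% length(pool) + 1L]
  }
  # half of the B_absent targets truly lack a probeset, half sit below the
  # detection threshold
  b_absent <- which(class_vec == "B_absent")
  off_chip <- b_absent[seq_along(b_absent) %% 2L == 1L]

  # coupled signal centred on the regulator's realised expression
  coupled <- function(reg, effect) {
    e <- mir_expr[reg, ]
    delta <- mean(e[true_grp == "fast"]) - mean(e[true_grp == "slow"])
    beta <- effect / abs(delta)
    -beta * (e - mean(e))
  }
  target_dir <- ifelse(is.na(regulators), NA_character_,
                       ifelse(regulators %in% mir_up, "down", "up"))

  # --- mRNA expression matrix ----------------------------------------------
  ps_rows <- list()
  annotation <- list()
  for (i in seq_len(n_genes)) {
    g <- genes[i]
    if (i %in% off_chip) next
    lo <- i %in% b_absent && !(i %in% off_chip)
    base <- if (lo) stats::runif(1, 4.5, 6) else stats::runif(1, 7, 12)
    sig <- rep(base, n)
    if (class_vec[i] %in% c("B_mrna_only", "B_dual")) {
      sig <- sig + coupled(regulators[i], cfg$mrna_log2_effect)
    }
    ps <- paste0("PS_", g)
    ps_rows[[ps]] <- sig + stats::rnorm(n, 0, cfg$sd_array)
    annotation[[ps]] <- g
    # a second, lower-expressed probeset for some null genes exercises dedup
    if (class_vec[i] == "null" && i %% 12L == 0L) {
      ps2 <- paste0("PS2_", g)
      ps_rows[[ps2]] <- sig - 1 + stats::rnorm(n, 0, cfg$sd_array)
      annotation[[ps2]] <- g
    }
  }
  for (j in seq_len(cfg$n_unannotated)) {
    ps <- sprintf("UNANN%03d_at", j)
    base <- stats::runif(1, if (j %% 3L == 0L) 4 else 7,
                         if (j %% 3L == 0L) 6 else 11)
    ps_rows[[ps]] <- base + stats::rnorm(n, 0, cfg$sd_array)
    annotation[[ps]] <- NA_character_
  }
  expr <- do.call(rbind, ps_rows)
  colnames(expr) <- clones
  annotation <- data.frame(probeset = names(annotation),
                           gene = unlist(annotation, use.names = FALSE),
                           stringsAsFactors = FALSE)

  # --- proteins and peptide table ------------------------------------------
  has_protein <- class_vec %in% c("A", "B_absent", "B_dual") |
    (class_vec == "null" & seq_len(n_genes) <=
       cfg$n_group_a + cfg$n_group_b + cfg$n_null_proteins)
  prot_genes <- genes[has_protein]
  runs <- as.vector(t(outer(clones, seq_len(cfg$reps_proteomics),
                            function(cl, r) paste0(cl, "_R", r))))
  run_map <- data.frame(run = runs,
                        clone = rep(clones, each = cfg$reps_proteomics),
                        stringsAsFactors = FALSE)
  prot_base <- stats::runif(length(prot_genes), 10, 14)
  prot_clone_log2 <- matrix(rep(prot_base, n), length(prot_genes), n,
                            dimnames = list(prot_genes, clones))
  for (i in seq_along(prot_genes)) {
    gi <- match(prot_genes[i], genes)
    if (class_vec[gi] %in% c("A", "B_absent", "B_dual")) {
      prot_clone_log2[i, ] <- prot_clone_log2[i, ] +
        coupled(regulators[gi], cfg$protein_log2_effect)
    }
  }
  pep_rows <- list()
  pep_id <- 0L
  add_pep <- function(protein, weight, charge, isotopes, ion_score, unique,
                      anova_p, signal_log2) {
    pep_id <<- pep_id + 1L
    ab <- weight * 2^(signal_log2[run_map$clone] +
                        stats::rnorm(length(runs), 0, cfg$sd_protein))
    row <- data.frame(peptide = sprintf("PEP%05d", pep_id),
                      protein = protein, charge = charge,
                      isotopes = isotopes, ion_score = ion_score,
                      unique = unique, anova_p = anova_p,
                      stringsAsFactors = FALSE)
    row[runs] <- as.list(unname(ab))
    pep_rows[[length(pep_rows) + 1L]] <<- row
  }
  for (i in seq_along(prot_genes)) {
    gi <- match(prot_genes[i], genes)
    sig <- prot_clone_log2[i, ]
    # one null protein with a single peptide exercises the min-peptide rule
    n_pep <- if (class_vec[gi] == "null" && i == length(prot_genes)) 1L
    else 2L + (i %% 3L)
    weights <- c(1, 0.6, 0.4, 0.25, 0.15)[seq_len(n_pep)]
    for (jj in seq_len(n_pep)) {
      add_pep(prot_genes[i], weights[jj], charge = (jj - 1L) %% 3L + 1L,
              isotopes = 4L + jj %% 3L,
              ion_score = if (jj == 1L) 30 else 30 + 5 * jj,
              unique = TRUE, anova_p = NA_real_, signal_log2 = sig)
    }
    # shared and filter-failing decoy peptides on a rotating subset
    if (i %% 4L == 1L) {
      add_pep(prot_genes[i], 2, 2L, 5L, 45, unique = FALSE,
              anova_p = NA_real_, signal_log2 = sig)
    }
    if (i %% 5L == 1L) {
      add_pep(prot_genes[i], 0.5, 4L, 5L, 45, TRUE, NA_real_, sig)     # charge
      add_pep(prot_genes[i], 0.5, 2L, 3L, 45, TRUE, NA_real_, sig)     # isotopes
      add_pep(prot_genes[i], 0.5, 2L, 5L, 25, TRUE, NA_real_, sig)     # ion score
      add_pep(prot_genes[i], 0.5, 2L, 5L, 45, TRUE, 0.5, sig)          # anova p
    }
  }
  peptides <- do.call(rbind, c(pep_rows, list(make.row.names = FALSE)))

  # --- target predictions ---------------------------------------------------
  edges <- data.frame(mirna = regulators[planted], gene = genes[planted],
                      stringsAsFactors = FALSE)
  pred <- data.frame(
    mirna_family = mirna_family_name(edges$mirna), gene = edges$gene,
    conserved = rep(TRUE, nrow(edges)),
    context_score = round(stats::runif(nrow(edges), -0.6, -0.05), 3),
    stringsAsFactors = FALSE
  )
  n_decoy <- round(cfg$decoy_rate * nrow(edges))
  if (n_decoy > 0) {
    dm <- sample(assays, n_decoy, replace = TRUE)
    dg <- sample(genes, n_decoy, replace = TRUE)
    keep <- !paste(dm, dg) %in% paste(edges$mirna, edges$gene)
    decoys <- data.frame(
      mirna_family = mirna_family_name(dm[keep]), gene = dg[keep],
      conserved = stats::runif(sum(keep)) < 0.5,
      context_score = round(stats::runif(sum(keep), -0.6, -0.05), 3),
      stringsAsFactors = FALSE
    )
    pred <- rbind(pred, decoys)
  }
  pred <- pred[!duplicated(pred[, c("mirna_family", "gene")]), , drop = FALSE]
  rownames(pred) <- NULL

  # --- term sets ------------------------------------------------------------
  null_genes <- genes[class_vec == "null"]
  gmt <- list(
    TERM_REPRESSED = unique(c(genes[class_vec == "A"],
                              utils::head(null_genes, 5))),
    TERM_MIXED = unique(c(genes[class_vec != "null" & class_vec != "A"],
                          utils::head(null_genes, 8))),
    TERM_NULL_1 = null_genes[seq_len(min(25, length(null_genes)))],
    TERM_NULL_2 = rev(null_genes)[seq_len(min(25, length(null_genes)))]
  )
  attr(gmt, "names_desc") <- list(
    TERM_REPRESSED = "planted translational repression targets",
    TERM_MIXED = "planted mixed-evidence targets",
    TERM_NULL_1 = "unregulated set 1", TERM_NULL_2 = "unregulated set 2"
  )

  truth <- list(
    mirnas = data.frame(
      assay = assays,
      class = c(rep("up", cfg$n_mirna_up), rep("down", cfg$n_mirna_down),
                rep("null", cfg$n_mirna_null)),
      stringsAsFactors = FALSE
    ),
    targets = data.frame(
      gene = genes, class = class_vec, direction = target_dir,
      regulator = regulators,
      off_chip = seq_len(n_genes) %in% off_chip,
      has_protein = has_protein, stringsAsFactors = FALSE
    ),
    edges = edges
  )
  structure(list(samples = samples, run_map = run_map, ct = ct, expr = expr,
                 annotation = annotation, peptides = peptides, runs = runs,
                 predictions = pred, gmt = gmt, truth = truth, config = cfg),
            class = "sim_bundle")
}

#' Write a simulated bundle to a directory of plain-text files
#'
#' Serialises every component in the pipeline's input formats (TSV matrices
#' and tables, GMT term sets). The same configuration and seed always
#' produce byte-identical files.
#'
#' @param bundle A `sim_bundle` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$samples, file.path(dir, "samples.tsv"))
  write_tsv(bundle$run_map, file.path(dir, "run_map.tsv"))
  write_matrix_tsv(bundle$ct, file.path(dir, "ct_matrix.tsv"))
  write_matrix_tsv(bundle$expr, file.path(dir, "expr_matrix.tsv"))
  write_tsv(bundle$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(bundle$peptides, file.path(dir, "peptides.tsv"))
  write_tsv(bundle$predictions, file.path(dir, "predictions.tsv"))
  write_gmt(bundle$gmt, file.path(dir, "terms.gmt"))
  write_tsv(bundle$truth$mirnas, file.path(dir, "truth_mirnas.tsv"))
  write_tsv(bundle$truth$targets, file.path(dir, "truth_targets.tsv"))
  write_tsv(bundle$truth$edges, file.path(dir, "truth_edges.tsv"))
  invisible(dir)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param dir Directory holding the bundle files.
#' @return A `sim_bundle`-shaped list (without the originating config).
#' @export
read_bundle <- function(dir) {
  peptides <- read_tsv(file.path(dir, "peptides.tsv"))
  run_map <- read_tsv(file.path(dir, "run_map.tsv"))
  structure(list(
    samples = read_tsv(file.path(dir, "samples.tsv")),
    run_map = run_map,
    ct = read_matrix_tsv(file.path(dir, "ct_matrix.tsv")),
    expr = read_matrix_tsv(file.path(dir, "expr_matrix.tsv")),
    annotation = read_tsv(file.path(dir, "annotation.tsv")),
    peptides = peptides,
    runs = run_map$run,
    predictions = read_tsv(file.path(dir, "predictions.tsv")),
    gmt = read_gmt(file.path(dir, "terms.gmt")),
    truth = list(
      mirnas = read_tsv(file.path(dir, "truth_mirnas.tsv")),
      targets = read_tsv(file.path(dir, "truth_targets.tsv")),
      edges = read_tsv(file.path(dir, "truth_edges.tsv"))
    )
  ), class = "sim_bundle")
}

#' Score pipeline output against the planted truth
#'
#' Set-comparison metrics per layer: sensitivity (planted features
#' recovered) and false-discovery fraction (called features not planted),
#' for the miRNA priority set, gene-level mRNA DE, protein DE and the
#' emitted interaction edges.
#'
#' @param result Pipeline result from [run_pipeline()].
#' @param truth Truth ledger from the same bundle.
#' @return Data frame: `layer`, `n_true`, `n_called`, `n_recovered`,
#'   `sensitivity`, `fdr`.
#' @export
score_recovery <- function(result, truth) {
  score_set <- function(called, planted) {
    hit <- sum(called %in% planted)
    data.frame(
      n_true = length(planted), n_called = length(called), n_recovered = hit,
      sensitivity = if (length(planted)) hit / length(planted) else NA_real_,
      fdr = if (length(called)) 1 - hit / length(called) else NA_real_
    )
  }
  tg <- truth$targets
  layers <- rbind(
    cbind(layer = "mirna_priority",
          score_set(result$mirna$assay[result$mirna$priority],
                    truth$mirnas$assay[truth$mirnas$class != "null"])),
    cbind(layer = "mrna_de",
          score_set(result$mrna_gene$gene,
                    tg$gene[tg$class %in% c("B_mrna_only", "B_dual")])),
    cbind(layer = "protein_de",
          score_set(result$protein$protein[result$protein$de],
                    tg$gene[tg$class %in% c("A", "B_absent", "B_dual")])),
    cbind(layer = "edges",
          score_set(paste(result$edges$mirna, result$edges$candidate),
                    paste(truth$edges$mirna, truth$edges$gene)))
  )
  rownames(layers) <- NULL
  layers
}
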