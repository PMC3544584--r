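#' Map DE proteins to microarray probesets
#'
#' For each differentially expressed protein (identified by gene symbol),
#' lists the probesets annotated to that symbol and selects the probeset
#' with the highest mean log2 expression across all samples as the
#' representative; ties are broken by lexicographically smallest probeset
#' id. Proteins whose symbol matches no probeset are marked absent from the
#' chip.
#'
#' @param de_proteins Protein DE table ([test_protein_de()]); `protein` must
#'   be the gene symbol used in `annotation`.
#' @param annotation Data frame `probeset`, `gene`.
#' @param expr Full log2 expression matrix (all probesets x samples).
#' @return Data frame per DE protein: `protein`, `n_probesets`,
#'   `representative` (`NA` when absent), `rep_mean_expr`, `absent_from_chip`.
#' @export
map_proteins <- function(de_proteins, annotation, expr) {
  prots <- de_proteins$protein[de_proteins$de]
  empty_map <- data.frame(protein = character(), n_probesets = integer(),
                          representative = character(),
                          rep_mean_expr = numeric(),
                          absent_from_chip = logical(),
                          stringsAsFactors = FALSE)
  if (length(prots) == 0L) return(empty_map)
  mean_expr <- rowMeans(expr)
  rows <- lapply(prots, function(pr) {
    ps <- annotation$probeset[annotation$gene %in% pr]
    ps <- ps[ps %in% rownames(expr)]
    if (length(ps) == 0L) {
      return(data.frame(protein = pr, n_probesets = 0L,
                        representative = NA_character_,
                        rep_mean_expr = NA_real_, absent_from_chip = TRUE,
                        stringsAsFactors = FALSE))
    }
    me <- mean_expr[ps]
    ord <- order(-me, ps)
    data.frame(protein = pr, n_probesets = length(ps),
               representative = ps[ord[1]], rep_mean_expr = unname(me[ord[1]]),
               absent_from_chip = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Classify cross-layer candidates into Groups A and B
#'
#' Every DE protein and every gene-level DE mRNA receives exactly one label.
#' Group A — the translational-repression signature — requires protein DE
#' with the representative probeset detected on the array but not
#' differentially expressed. Group B collects the remaining evidence
#' patterns: (1) protein DE with the probeset undetected or absent from the
#' chip, (2) mRNA DE with no DE protein observed, (3) DE at both the mRNA
#' and protein level (concordant or discordant). Whenever protein evidence
#' exists, the direction carried into target overlap is the protein's.
#'
#' @param de_proteins Protein DE table ([test_protein_de()]).
#' @param de_mrnas_gene Gene-level mRNA DE table ([annotate_and_dedupe()]).
#' @param detected_ids Character vector of detected probeset ids.
#' @param map Protein-to-probeset map ([map_proteins()]).
#' @return Data frame per candidate: `candidate` (gene symbol), flags
#'   `protein_de`, `mrna_present_on_chip`, `mrna_detected`, `mrna_de`,
#'   `protein_direction`, `mrna_direction`, `group` (`"A"`/`"B"`),
#'   `direction_used`, `reason`.
#' @export
classify <- function(de_proteins, de_mrnas_gene, detected_ids, map) {
  prot <- de_proteins[de_proteins$de, , drop = FALSE]
  if (anyDuplicated(prot$protein) || anyDuplicated(de_mrnas_gene$gene)) {
    stop("classify: duplicate candidate ids in input tables")
  }
  mrna_genes <- de_mrnas_gene$gene
  cand <- union(prot$protein, mrna_genes)
  pi <- match(cand, prot$protein)
  mi <- match(cand, de_mrnas_gene$gene)
  ki <- match(cand, map$protein)

  protein_de <- !is.na(pi)
  mrna_de <- !is.na(mi)
  on_chip <- ifelse(protein_de, !is.na(ki) & !map$absent_from_chip[ki],
                    TRUE)  # mRNA-only candidates are on-chip by construction
  rep_ps <- ifelse(!is.na(ki), map$representative[ki], NA_character_)
  detected <- ifelse(protein_de, !is.na(rep_ps) & rep_ps %in% detected_ids,
                     mrna_de)  # DE mRNA is detected by construction

  group <- character(length(cand))
  reason <- character(length(cand))
  a <- protein_de & detected & !mrna_de
  group[a] <- "A"
  reason[a] <- "protein DE; mRNA detected, not DE (translational repression)"
  b1 <- protein_de & !detected & !mrna_de
  group[b1] <- "B"
  reason[b1] <- ifelse(!on_chip[b1],
                       "protein DE; probeset absent from chip",
                       "protein DE; probeset below detection threshold")
  b2 <- !protein_de & mrna_de
  group[b2] <- "B"
  reason[b2] <- "mRNA DE; protein not identified"
  b3 <- protein_de & mrna_de
  group[b3] <- "B"
  reason[b3] <- "DE at both mRNA and protein level"

  protein_direction <- ifelse(protein_de, prot$direction[pi], NA_character_)
  mrna_direction <- ifelse(mrna_de, de_mrnas_gene$direction[mi], NA_character_)
  direction_used <- ifelse(protein_de, protein_direction, mrna_direction)

  data.frame(
    candidate = cand, protein_de = protein_de,
    mrna_present_on_chip = on_chip, mrna_detected = detected,
    mrna_de = mrna_de, protein_direction = protein_direction,
    mrna_direction = mrna_direction, group = group,
    direction_used = direction_used, reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Anti-correlated conserved-target overlap
#'
#' Emits an interaction edge for every (priority miRNA, Group A/B candidate)
#' pair that appears in the conserved target-prediction table with opposite
#' regulation directions (miRNA up with growth paired only with
#' down-regulated candidates and vice versa). Edges are ranked within each
#' miRNA by ascending total context+ score (more negative = stronger
#' predicted repression).
#'
#' @param candidates Classification table ([classify()]).
#' @param mirnas miRNA priority table ([prioritize()]).
#' @param predictions Data frame with columns `mirna_family`, `gene`,
#'   `conserved` (logical), `context_score` (<= 0).
#' @param family_map Optional named character vector mapping mature miRNA
#'   ids to prediction-table family names; ids not covered fall back to
#'   [mirna_family_name()].
#' @return Data frame of edges: `mirna`, `candidate`, `group`,
#'   `mirna_direction`, `candidate_direction`, `context_score`, `rank`.
#'   Attributes: `"summary"` (per-group candidate counts and fraction with
#'   >= 1 edge), `"unmatched_mirnas"` (priority miRNAs absent from the
#'   prediction table, excluded).
#' @export
overlap <- function(candidates, mirnas, predictions, family_map = NULL) {
  pri <- mirnas[mirnas$priority, , drop = FALSE]
  cand <- candidates[candidates$group %in% c("A", "B"), , drop = FALSE]
  preds <- predictions[as.logical(predictions$conserved), , drop = FALSE]
  fam <- mirna_family_name(pri$assay, family_map)
  matched <- fam %in% preds$mirna_family
  unmatched <- pri$assay[!matched]
  edges <- list()
  for (i in which(matched)) {
    hit <- preds[preds$mirna_family == fam[i], , drop = FALSE]
    opp <- if (identical(pri$direction[i], "up")) "down" else "up"
    tg <- cand[cand$candidate %in% hit$gene &
                 cand$direction_used %in% opp, , drop = FALSE]
    if (nrow(tg) == 0L) next
    sc <- hit$context_score[match(tg$candidate, hit$gene)]
    ord <- order(sc, tg$candidate)
    edges[[length(edges) + 1L]] <- data.frame(
      mirna = pri$assay[i], candidate = tg$candidate[ord],
      group = tg$group[ord], mirna_direction = pri$direction[i],
      candidate_direction = tg$direction_used[ord],
      context_score = sc[ord], rank = seq_along(ord),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(edges)) {
    do.call(rbind, c(edges, list(make.row.names = FALSE)))
  } else {
    data.frame(mirna = character(), candidate = character(),
               group = character(), mirna_direction = character(),
               candidate_direction = character(), context_score = numeric(),
               rank = integer(), stringsAsFactors = FALSE)
  }
  smry <- do.call(rbind, lapply(c("A", "B"), function(g) {
    ids <- cand$candidate[cand$group == g]
    hit <- sum(ids %in% out$candidate)
    data.frame(group = g, n_candidates = length(ids), n_with_edge = hit,
               fraction_with_edge = if (length(ids)) hit / length(ids)
               else NA_real_, stringsAsFactors = FALSE)
  }))
  attr(out, "summary") <- smry
  attr(out, "unmatched_mirnas") <- unmatched
  out
}

#' Canonical family name for a mature miRNA id
#'
#' Strips a species prefix (e.g. `hsa-`, `mmu-`, `rno-`, `cgr-`), a trailing
#' arm suffix (`-3p`/`-5p`) and a trailing star marker (`*`), yielding the
#' family key used by prediction tables. Entries of `family_map` override
#' the rule.
#'
#' @param ids Character vector of mature miRNA ids.
#' @param family_map Optional named character vector of explicit overrides.
#' @return Character vector of family names.
#' @export
mirna_family_name <- function(ids, family_map = NULL) {
  out <- sub("^[a-z]{3}-", "", ids)
  out <- sub("\\*$", "", out)
  out <- sub("-(3p|5p)$", "", out)
  if (!is.null(family_map)) {
    hit <- ids %in% names(family_map)
    out[hit] <- unname(family_map[ids[hit]])
  }
  out
}

#' Write a bipartite interaction network to edge and node tables
#'
#' Serialises the miRNA-candidate network as a tab-separated edge list and a
#' node-attribute table; [read_network()] round-trips them losslessly.
#'
#' @param edges Edge data frame from [overlap()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
export_network <- function(edges, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edge_path <- file.path(dir, "edges.tsv")
  node_path <- file.path(dir, "nodes.tsv")
  write_tsv(as.data.frame(edges)[, c("mirna", "candidate", "group",
                                     "mirna_direction", "candidate_direction",
                                     "context_score", "rank")], edge_path)
  mir_ids <- unique(edges$mirna)
  cand_ids <- unique(edges$candidate)
  nodes <- rbind(
    data.frame(id = mir_ids, type = rep("miRNA", length(mir_ids)),
               direction = edges$mirna_direction[match(mir_ids, edges$mirna)],
               stringsAsFactors = FALSE),
    data.frame(id = cand_ids, type = rep("candidate", length(cand_ids)),
               direction = edges$candidate_direction[
                 match(cand_ids, edges$candidate)],
               stringsAsFactors = FALSE)
  )
  write_tsv(nodes, node_path)
  invisible(c(edges = edge_path, nodes = node_path))
}

#' Read a network written by [export_network()]
#'
#' @param dir Directory holding `edges.tsv` and `nodes.tsv`.
#' @return List with `edges` and `nodes` data frames.
#' @export
read_network <- function(dir) {
  list(edges = read_tsv(file.path(dir, "edges.tsv")),
       nodes = read_tsv(file.path(dir, "nodes.tsv")))
}
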