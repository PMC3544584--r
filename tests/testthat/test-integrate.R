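# Small constructed stage-1 outputs used across the classification tests.
protein_row <- function(protein, de = TRUE, direction = "up") {
  data.frame(protein = protein, n_peptides = 3L,
             log2fc = if (direction == "up") 0.6 else -0.6,
             fc = 2^(if (direction == "up") 0.6 else -0.6),
             p = 0.001, q = 0.01, de = de, direction = direction,
             excluded_few_peptides = FALSE, stringsAsFactors = FALSE)
}

gene_row <- function(gene, direction = "down") {
  data.frame(gene = gene, probeset = paste0("PS_", gene),
             log2fc = if (direction == "up") 0.5 else -0.5,
             fc = 2^(if (direction == "up") 0.5 else -0.5),
             mean_expr = 9, p = 0.001, q = 0.01, direction = direction,
             n_probesets = 1L, direction_conflict = FALSE,
             stringsAsFactors = FALSE)
}

empty_genes <- function() gene_row("x")[0, ]

test_that("representative probeset is the highest expressed, ties lexicographic", {
  expr <- rbind(P1 = rep(8.2, 4), P2 = rep(10.1, 4), P3 = rep(10.1, 4))
  colnames(expr) <- paste0("S", 1:4)
  ann <- data.frame(probeset = c("P1", "P2", "P3"),
                    gene = c("G1", "G1", "G1"), stringsAsFactors = FALSE)
  map <- map_proteins(protein_row("G1"), ann, expr)
  expect_equal(map$representative, "P2")  # P2 before P3 at equal mean
  # protein with no probeset is absent from chip
  map2 <- map_proteins(protein_row("G9"), ann, expr)
  expect_true(map2$absent_from_chip)
  expect_true(is.na(map2$representative))
})

test_that("classification reproduces the full evidence truth table", {
  expr <- rbind(PS_A = rep(9, 4), PS_B = rep(5, 4))
  colnames(expr) <- paste0("S", 1:4)
  ann <- data.frame(probeset = c("PS_A", "PS_B"), gene = c("GA", "GB"),
                    stringsAsFactors = FALSE)
  detected <- "PS_A"

  # protein DE, probeset detected, mRNA not DE -> Group A
  mapA <- map_proteins(protein_row("GA", direction = "down"), ann, expr)
  clsA <- classify(protein_row("GA", direction = "down"), empty_genes(),
                   detected, mapA)
  expect_equal(clsA$group, "A")
  expect_equal(clsA$direction_used, "down")

  # protein DE, probeset below detection -> Group B (clause 1)
  mapB <- map_proteins(protein_row("GB"), ann, expr)
  clsB <- classify(protein_row("GB"), empty_genes(), detected, mapB)
  expect_equal(clsB$group, "B")
  expect_match(clsB$reason, "below detection")

  # protein DE, absent from chip -> Group B (clause 1), protein direction kept
  mapC <- map_proteins(protein_row("GC"), ann, expr)
  clsC <- classify(protein_row("GC"), empty_genes(), detected, mapC)
  expect_equal(clsC$group, "B")
  expect_match(clsC$reason, "absent from chip")
  expect_equal(clsC$direction_used, "up")

  # mRNA DE without protein -> Group B (clause 2), mRNA direction used
  clsD <- classify(protein_row("GZ", de = FALSE), gene_row("GD", "down"),
                   c(detected, "PS_GD"), map_proteins(
                     protein_row("GZ", de = FALSE), ann, expr))
  expect_equal(clsD$group[clsD$candidate == "GD"], "B")
  expect_equal(clsD$direction_used[clsD$candidate == "GD"], "down")

  # DE at both levels, discordant -> Group B (clause 3), protein direction
  mapE <- map_proteins(protein_row("GA", direction = "up"), ann, expr)
  clsE <- classify(protein_row("GA", direction = "up"), gene_row("GA", "down"),
                   detected, mapE)
  expect_equal(clsE$group, "B")
  expect_equal(clsE$direction_used, "up")
  expect_match(clsE$reason, "both")

  # DE at both levels, concordant -> still Group B clause 3
  clsF <- classify(protein_row("GA", direction = "up"), gene_row("GA", "up"),
                   detected, mapE)
  expect_equal(clsF$group, "B")

  # not DE anywhere -> no candidate rows at all
  cls0 <- classify(protein_row("GA", de = FALSE), empty_genes(), detected,
                   map_proteins(protein_row("GA", de = FALSE), ann, expr))
  expect_equal(nrow(cls0), 0L)
})

test_that("groups are exclusive and classification ignores input order", {
  expr <- rbind(PS_A = rep(9, 4), PS_B = rep(5, 4), PS_C = rep(9, 4))
  colnames(expr) <- paste0("S", 1:4)
  ann <- data.frame(probeset = c("PS_A", "PS_B", "PS_C"),
                    gene = c("GA", "GB", "GC"), stringsAsFactors = FALSE)
  prot <- rbind(protein_row("GA", direction = "down"), protein_row("GB"),
                protein_row("GC"))
  genes <- gene_row("GC", "down")
  detected <- c("PS_A", "PS_C")
  map <- map_proteins(prot, ann, expr)
  cls <- classify(prot, genes, detected, map)
  expect_true(all(cls$group %in% c("A", "B")))
  expect_equal(sort(cls$candidate), c("GA", "GB", "GC"))
  # permuted input order gives identical assignments
  cls2 <- classify(prot[3:1, ], genes, detected, map[3:1, ])
  m <- match(cls$candidate, cls2$candidate)
  expect_equal(cls$group, cls2$group[m])
  expect_equal(cls$direction_used, cls2$direction_used[m])
  expect_error(classify(rbind(prot, prot[1, ]), genes, detected, map),
               "duplicate")
})

test_that("overlap emits only anti-correlated conserved predictions, ranked", {
  cand <- data.frame(
    candidate = c("GA", "GB", "GC"), protein_de = TRUE,
    mrna_present_on_chip = TRUE, mrna_detected = TRUE, mrna_de = FALSE,
    protein_direction = c("down", "down", "up"),
    mrna_direction = NA_character_, group = c("A", "A", "B"),
    direction_used = c("down", "down", "up"), reason = "",
    stringsAsFactors = FALSE
  )
  mir <- data.frame(assay = c("hsa-miR-1", "hsa-miR-2"), ddct = 0,
                    fc = c(1.6, 0.6), log2fc = c(0.7, -0.7), n_fast = 5,
                    n_slow = 5, tested = TRUE, p = 0.001, q = 0.01, de = TRUE,
                    direction = c("up", "down"), pcc_expr = c(0.8, -0.8),
                    pcc_dct = c(-0.8, 0.8), priority = TRUE,
                    stringsAsFactors = FALSE)
  preds <- data.frame(
    mirna_family = c("miR-1", "miR-1", "miR-1", "miR-2", "miR-3"),
    gene = c("GA", "GB", "GC", "GC", "GA"),
    conserved = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    context_score = c(-0.2, -0.5, -0.3, -0.4, -0.6),
    stringsAsFactors = FALSE
  )
  edges <- overlap(cand, mir, preds)
  # miR-1 (up): GA and GB (down) match; GC (up) violates anti-correlation;
  # miR-2 -> GC is not conserved
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$candidate, c("GB", "GA"))  # ranked by ascending score
  expect_equal(edges$rank, c(1L, 2L))
  expect_true(all(edges$mirna_direction != edges$candidate_direction))
  smry <- attr(edges, "summary")
  expect_equal(smry$fraction_with_edge[smry$group == "A"], 1)
  expect_equal(smry$fraction_with_edge[smry$group == "B"], 0)
})

test_that("priority miRNAs missing from the prediction table are logged", {
  cand <- data.frame(candidate = "GA", protein_de = TRUE,
                     mrna_present_on_chip = TRUE, mrna_detected = TRUE,
                     mrna_de = FALSE, protein_direction = "down",
                     mrna_direction = NA_character_, group = "A",
                     direction_used = "down", reason = "",
                     stringsAsFactors = FALSE)
  mir <- data.frame(assay = "hsa-miR-99*", ddct = 0, fc = 1.6, log2fc = 0.7,
                    n_fast = 5, n_slow = 5, tested = TRUE, p = 0.001,
                    q = 0.01, de = TRUE, direction = "up", pcc_expr = 0.8,
                    pcc_dct = -0.8, priority = TRUE, stringsAsFactors = FALSE)
  preds <- data.frame(mirna_family = "miR-1", gene = "GA", conserved = TRUE,
                      context_score = -0.3, stringsAsFactors = FALSE)
  edges <- overlap(cand, mir, preds)
  expect_equal(nrow(edges), 0L)
  expect_equal(attr(edges, "unmatched_mirnas"), "hsa-miR-99*")
})

test_that("family naming strips species prefix, star and arm suffix", {
  expect_equal(mirna_family_name("hsa-miR-338-3p"), "miR-338")
  expect_equal(mirna_family_name("mmu-miR-17"), "miR-17")
  expect_equal(mirna_family_name("hsa-miR-20a*"), "miR-20a")
  expect_equal(mirna_family_name("rno-let-7a-5p"), "let-7a")
  expect_equal(mirna_family_name("hsa-miR-1", c(`hsa-miR-1` = "custom")),
               "custom")
})

test_that("network export round-trips losslessly, including empty networks", {
  edges <- data.frame(
    mirna = c("m1", "m1", "m2"), candidate = c("GA", "GB", "GC"),
    group = c("A", "A", "B"), mirna_direction = c("up", "up", "down"),
    candidate_direction = c("down", "down", "up"),
    context_score = c(-0.5, -0.2, -0.4), rank = c(1L, 2L, 1L),
    stringsAsFactors = FALSE
  )
  dir <- withr::local_tempdir()
  export_network(edges, dir)
  back <- read_network(dir)
  expect_equal(back$edges, edges)
  expect_setequal(back$nodes$id, c("m1", "m2", "GA", "GB", "GC"))
  # empty network still writes valid files with headers
  dir2 <- withr::local_tempdir()
  export_network(edges[0, ], dir2)
  back2 <- read_network(dir2)
  expect_equal(nrow(back2$edges), 0L)
  expect_equal(names(back2$edges), names(edges))
})
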