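test_that("configuration validation rejects infeasible designs", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, n_fast = -1), "non-negative")
  expect_error(sim_config(seed = 1, fast_cutoff = 0.02, slow_cutoff = 0.023),
               "below fast_cutoff")
  expect_error(sim_config(seed = 1, n_mirna_up = 0, n_mirna_down = 0),
               "planted miRNA")
  expect_error(sim_config(seed = 1, fast_cutoff = 0.2), "growth range")
})

test_that("the same seed yields a byte-identical bundle on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(simulate_study(small_config(31)), d1)
  write_bundle(simulate_study(small_config(31)), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10)
  h1 <- unname(tools::md5sum(file.path(d1, files)))
  h2 <- unname(tools::md5sum(file.path(d2, files)))
  expect_equal(h1, h2)
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_bundle(simulate_study(small_config(32)), d3)
  h3 <- unname(tools::md5sum(file.path(d3, files)))
  expect_false(all(h1 == h3))
})

test_that("a written bundle parses back into equal structures", {
  b <- simulate_study(small_config(41))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  rb <- read_bundle(dir)
  expect_equal(rb$ct, b$ct)
  expect_equal(rb$expr, b$expr)
  expect_equal(rb$samples, b$samples)
  expect_equal(rb$annotation, b$annotation)
  expect_equal(rb$predictions, b$predictions)
  expect_equal(rb$truth$edges, b$truth$edges)
  expect_equal(sort(names(rb$gmt)), sort(names(b$gmt)))
  expect_equal(rb$gmt[["TERM_REPRESSED"]], b$gmt[["TERM_REPRESSED"]])
  expect_equal(rb$peptides$peptide, b$peptides$peptide)
  expect_equal(rb$peptides[[rb$runs[1]]], b$peptides[[b$runs[1]]],
               tolerance = 1e-12)
})

test_that("the bundle honours the configured study design", {
  cfg <- small_config(51)
  b <- simulate_study(cfg)
  expect_equal(nrow(b$samples), cfg$n_fast + cfg$n_slow)
  grp <- assign_groups(b$samples, cfg$fast_cutoff, cfg$slow_cutoff)
  expect_equal(sum(grp$group == "fast"), cfg$n_fast)
  expect_equal(sum(grp$group == "slow"), cfg$n_slow)
  expect_true(all(b$samples$growth_rate >= cfg$growth_range[1] &
                    b$samples$growth_rate <= cfg$growth_range[2]))
  expect_true(cfg$reference_assay %in% rownames(b$ct))
  expect_equal(nrow(b$truth$mirnas),
               cfg$n_mirna_up + cfg$n_mirna_down + cfg$n_mirna_null)
  # every planted edge references a planted miRNA and a planted target
  expect_true(all(b$truth$edges$mirna %in%
                    b$truth$mirnas$assay[b$truth$mirnas$class != "null"]))
  expect_true(all(b$truth$edges$gene %in%
                    b$truth$targets$gene[b$truth$targets$class != "null"]))
  # planted edges all appear as conserved predictions
  key <- paste(mirna_family_name(b$truth$edges$mirna), b$truth$edges$gene)
  pk <- paste(b$predictions$mirna_family[b$predictions$conserved],
              b$predictions$gene[b$predictions$conserved])
  expect_true(all(key %in% pk))
})

test_that("recovery scoring equals hand-computed set arithmetic", {
  truth <- list(
    mirnas = data.frame(assay = c("m1", "m2", "m3", "m4"),
                        class = c("up", "down", "null", "null")),
    targets = data.frame(gene = c("g1", "g2", "g3"),
                         class = c("A", "B_dual", "null")),
    edges = data.frame(mirna = c("m1", "m2"), gene = c("g1", "g2"))
  )
  result <- list(
    mirna = data.frame(assay = c("m1", "m3"), priority = TRUE),
    mrna_gene = data.frame(gene = "g2"),
    protein = data.frame(protein = c("g1", "g2"), de = c(TRUE, FALSE)),
    edges = data.frame(mirna = "m1", candidate = "g1")
  )
  sc <- score_recovery(result, truth)
  get <- function(l, f) sc[[f]][sc$layer == l]
  expect_equal(get("mirna_priority", "sensitivity"), 0.5)  # m1 of {m1,m2}
  expect_equal(get("mirna_priority", "fdr"), 0.5)          # m3 is a false call
  expect_equal(get("mrna_de", "sensitivity"), 1)           # g2 of {g2}
  expect_equal(get("protein_de", "sensitivity"), 0.5)      # g1 of {g1,g2}
  expect_equal(get("edges", "sensitivity"), 0.5)
  expect_equal(get("edges", "fdr"), 0)
  # perfect and empty cases
  perfect <- list(mirna = data.frame(assay = c("m1", "m2"), priority = TRUE),
                  mrna_gene = data.frame(gene = "g2"),
                  protein = data.frame(protein = c("g1", "g2"),
                                       de = c(TRUE, TRUE)),
                  edges = data.frame(mirna = c("m1", "m2"),
                                     candidate = c("g1", "g2")))
  scp <- score_recovery(perfect, truth)
  expect_equal(scp$sensitivity, rep(1, 4))
  expect_equal(scp$fdr, rep(0, 4))
  empty <- list(mirna = data.frame(assay = character(), priority = logical()),
                mrna_gene = data.frame(gene = character()),
                protein = data.frame(protein = character(), de = logical()),
                edges = data.frame(mirna = character(),
                                   candidate = character()))
  expect_equal(score_recovery(empty, truth)$sensitivity, rep(0, 4))
})

test_that("stronger planted effects never lower mean edge sensitivity", {
  effects <- c(0.25, 0.5, 0.9)
  mean_sens <- vapply(effects, function(ef) {
    sens <- vapply(1:4, function(s) {
      cfg <- small_config(700 + s, protein_log2_effect = ef,
                          mrna_log2_effect = ef, sd_protein = 0.3,
                          sd_array = 0.35)
      b <- simulate_study(cfg)
      sc <- score_recovery(run_pipeline(b), b$truth)
      sc$sensitivity[sc$layer == "edges"]
    }, numeric(1))
    mean(sens)
  }, numeric(1))
  expect_true(all(diff(mean_sens) >= -1e-9))
})
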