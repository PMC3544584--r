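test_that("reference normalisation subtracts the reference Ct per sample", {
  ct <- toy_ct()
  dct <- normalize_ct(ct)
  expect_equal(rownames(dct), c("miR-a", "miR-b", "miR-ref-copy"))
  expect_equal(dct["miR-a", ], ct["miR-a", ] - ct["Mamm-U6", ])
  expect_equal(unname(dct["miR-ref-copy", ]), rep(0, 4))
  # hand arithmetic on the full toy matrix
  expect_equal(unname(dct["miR-b", ]), c(10, 9, 11, 10))
})

test_that("normalisation propagates missing wells and validates the reference", {
  ct <- toy_ct()
  ct["miR-a", 2] <- NA
  dct <- normalize_ct(ct)
  expect_true(is.na(dct["miR-a", 2]))
  ct["Mamm-U6", 3] <- NA
  expect_error(normalize_ct(ct), "finite in every sample")
  expect_error(normalize_ct(toy_ct(), "absent"), "not present")
})

test_that("ddCt fold change follows 2^-ddCt with reciprocity on group swap", {
  dct <- normalize_ct(toy_ct())
  grp <- toy_groups(4)
  fc <- ddct_fold_change(dct, grp)
  # miR-a dCt: fast (5,6), slow (4,7) -> ddct 0 -> FC 1
  expect_equal(fc$fc[fc$assay == "miR-a"], 1)
  # one-cycle shift doubles
  dct2 <- rbind(dct, shifted = c(4, 4, 5, 5))
  fc2 <- ddct_fold_change(dct2, grp)
  expect_equal(fc2$fc[fc2$assay == "shifted"], 2)
  swapped <- stats::setNames(ifelse(grp == "fast", "slow", "fast"), names(grp))
  fc_sw <- ddct_fold_change(dct2, swapped)
  expect_equal(fc2$fc * fc_sw$fc, rep(1, nrow(fc2)))
})

test_that("planted fold change is recovered within 10% at the study design", {
  # 1.5x true ratio = ddCt of -log2(1.5), Ct noise sd 0.1, 15 vs 15
  set.seed(202)
  n <- 30
  samples <- paste0("S", 1:n)
  grp <- stats::setNames(rep(c("fast", "slow"), each = 15), samples)
  dd <- log2(1.5)
  ct <- rbind(
    planted = 26 - ifelse(grp == "fast", dd, 0) + stats::rnorm(n, 0, 0.1),
    `Mamm-U6` = rep(20, n)
  )
  colnames(ct) <- samples
  fc <- ddct_fold_change(normalize_ct(ct), grp)
  expect_equal(fc$fc[fc$assay == "planted"], 1.5, tolerance = 0.1)
})

test_that("miRNA DE testing flags by inclusive FC and adjusted p", {
  set.seed(303)
  n <- 20
  samples <- paste0("S", 1:n)
  grp <- stats::setNames(rep(c("fast", "slow"), each = 10), samples)
  shift <- ifelse(grp == "fast", 1, 0)
  ct <- rbind(
    de_up = 25 - shift + stats::rnorm(n, 0, 0.1),
    flat1 = 27 + stats::rnorm(n, 0, 0.1),
    flat2 = 24 + stats::rnorm(n, 0, 0.1),
    `Mamm-U6` = 20 + stats::rnorm(n, 0, 0.01)
  )
  colnames(ct) <- samples
  de <- test_mirna_de(normalize_ct(ct), grp)
  expect_true(de$de[de$assay == "de_up"])
  expect_equal(de$direction[de$assay == "de_up"], "up")
  expect_false(any(de$de[de$assay %in% c("flat1", "flat2")]))
  # identical group means -> no calls
  ct0 <- ct
  ct0["de_up", ] <- 25
  de0 <- test_mirna_de(normalize_ct(ct0), grp)
  expect_equal(sum(de0$de), 0)
})

test_that("growth correlation is reported on the expression scale", {
  n <- 12
  samples <- paste0("S", 1:n)
  growth <- stats::setNames(seq(0.011, 0.044, length.out = n), samples)
  dct <- rbind(tracks = 8 - 100 * growth,   # dCt falls as growth rises
               anti = 3 + 100 * growth)
  colnames(dct) <- samples
  pcc <- growth_correlation(dct, growth)
  expect_equal(pcc$pcc_expr[pcc$assay == "tracks"], 1)
  expect_equal(pcc$pcc_expr[pcc$assay == "anti"], -1)
  expect_equal(pcc$pcc_dct, -pcc$pcc_expr)
})

test_that("a growth-independent assay rarely clears the correlation filter", {
  set.seed(404)
  n <- 30
  samples <- paste0("S", 1:n)
  growth <- stats::setNames(stats::runif(n, 0.011, 0.044), samples)
  hits <- 0L
  for (i in 1:50) {
    dct <- matrix(5 + stats::rnorm(n, 0, 0.2), 1,
                  dimnames = list("null_mir", samples))
    if (abs(growth_correlation(dct, growth)$pcc_expr) >= 0.4) hits <- hits + 1L
  }
  expect_lt(hits, 10)  # |PCC| >= 0.4 under the null is uncommon at n = 30
})

test_that("zero-variance assays are flagged NA and never prioritised", {
  n <- 10
  samples <- paste0("S", 1:n)
  growth <- stats::setNames(seq(0.01, 0.04, length.out = n), samples)
  dct <- matrix(rep(4, n), 1, dimnames = list("const", samples))
  pcc <- growth_correlation(dct, growth)
  expect_true(is.na(pcc$pcc_expr))
  de <- data.frame(assay = "const", ddct = 0, fc = 1, log2fc = 0,
                   n_fast = 5, n_slow = 5, tested = TRUE, p = 1, q = 1,
                   de = FALSE, direction = NA_character_)
  expect_false(prioritize(de, pcc)$priority)
})

test_that("prioritisation applies the inclusive |PCC| >= 0.4 boundary", {
  de <- data.frame(assay = c("m1", "m2", "m3", "m4"),
                   ddct = 0, fc = c(1.5, 1.5, 0.6, 1.5),
                   log2fc = c(0.58, 0.58, -0.74, 0.58),
                   n_fast = 5, n_slow = 5, tested = TRUE,
                   p = 0.001, q = c(0.01, 0.01, 0.01, 0.01),
                   de = c(TRUE, TRUE, TRUE, FALSE),
                   direction = c("up", "up", "down", "up"))
  pcc <- data.frame(assay = c("m1", "m2", "m3", "m4"),
                    pcc_expr = c(0.39, 0.40, -0.40, 0.99),
                    pcc_dct = -c(0.39, 0.40, -0.40, 0.99), n_used = 10)
  pri <- prioritize(de, pcc)
  expect_equal(pri$priority, c(FALSE, TRUE, TRUE, FALSE))
  part <- attr(pri, "partition")
  expect_equal(part$up, "m2")
  expect_equal(part$down, "m3")
  # priority set is a subset of the DE set; partition covers it disjointly
  expect_true(all(pri$de[pri$priority]))
  expect_length(intersect(part$up, part$down), 0)
  expect_setequal(c(part$up, part$down), pri$assay[pri$priority])
})
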