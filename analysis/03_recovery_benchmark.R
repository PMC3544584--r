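#!/usr/bin/env Rscript
# Recovery benchmark: how reliably does the pipeline recover the planted
# regulation?
#
# Scores the single-study run against its truth ledger, then repeats the
# simulate-and-run cycle over 20 seeds to estimate sensitivity and
# false-discovery fractions per layer, writing the summary to
# results/recovery.tsv. A noiseless, decoy-free configuration is also run
# as an identity check: it must return exactly the planted edge set.

library(miromics)

bundle <- read_bundle("results/bundle")
res <- run_pipeline(bundle)
single <- score_recovery(res, bundle$truth)
cat("Recovery for the seed-101 study:\n")
print(single, row.names = FALSE)

seeds <- 201:220
per_seed <- do.call(rbind, lapply(seeds, function(s) {
  b <- simulate_study(sim_config(seed = s))
  sc <- score_recovery(run_pipeline(b), b$truth)
  cbind(seed = s, sc)
}))
agg <- aggregate(per_seed[, c("sensitivity", "fdr")],
                 by = list(layer = per_seed$layer), FUN = mean)
cat("\nMean recovery over", length(seeds), "seeds:\n")
print(agg, row.names = FALSE)
write_tsv(per_seed, "results/recovery.tsv")

noiseless <- simulate_study(sim_config(seed = 101, sd_ct = 0, sd_array = 0,
                                       sd_protein = 0, decoy_rate = 0))
nres <- run_pipeline(noiseless)
exact <- setequal(paste(nres$edges$mirna, nres$edges$candidate),
                  paste(noiseless$truth$edges$mirna,
                        noiseless$truth$edges$gene))
cat("\nNoiseless identity check (emitted edges == planted edges):",
    exact, "\n")
cat("Per-seed table written to results/recovery.tsv\n")
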