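# Independent oracles and small constructed fixtures shared across tests.
# Every oracle here is deliberately written from the definition (explicit
# loops / enumeration), not by calling the code path it checks.

# Benjamini-Hochberg step-up by direct definition: for the p-value of rank i,
# q = min over ranks j >= i of p_(j) * m / j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q[o[i]] <- min(1, cand)
  }
  q
}

# Welch two-sample t-test from the textbook formulas.
welch_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                   (vb / length(b))^2 / (length(b) - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Hypergeometric upper tail by pmf summation.
hyper_oracle <- function(x, big_k, big_n, n) {
  ks <- x:min(big_k, n)
  sum(choose(big_k, ks) * choose(big_n - big_k, n - ks)) / choose(big_n, n)
}

# A small hand-sized Ct fixture: 3 assays + reference across 4 samples.
toy_ct <- function() {
  m <- matrix(c(25, 26, 24, 27,
                30, 29, 31, 30,
                20, 20, 20, 20,
                20, 20, 20, 20),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("miR-a", "miR-b", "miR-ref-copy", "Mamm-U6"),
                              paste0("S", 1:4)))
  m
}

# Balanced two-group sample labels for n samples named S1..Sn.
toy_groups <- function(n) {
  stats::setNames(rep(c("fast", "slow"), each = n / 2), paste0("S", seq_len(n)))
}

# Deterministic small bundle for pipeline-level tests (fast to generate).
small_config <- function(seed, ...) {
  sim_config(n_fast = 8, n_slow = 8, n_mirna_up = 4, n_mirna_down = 3,
             n_mirna_null = 12, n_group_a = 5, n_group_b = 6,
             n_null_genes = 40, n_null_proteins = 12, n_unannotated = 6,
             reps_proteomics = 2, seed = seed, ...)
}
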