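# miromics

Integrated miRNA / mRNA / protein differential-expression analysis of
clonal growth-rate variation.

## The problem

Panels of sister clones derived from a single transfection pool can span a
wide range of specific growth rates (mu, in h^-1, estimated as
`(ln d2 - ln d1) / (t2 - t1)` from paired cell-density measurements) while
holding most other biology constant. Profiling such a panel in parallel at
three layers — miRNA by qPCR low-density arrays, mRNA by microarray, and
protein by label-free LC-MS — makes it possible to ask which miRNAs track
growth rate and which of their predicted targets show the signature of
miRNA-mediated **translational repression**: a protein that changes between
fast and slow growers while its mRNA stays flat.

`miromics` implements that integration as a tested, reusable pipeline for
anyone analysing multi-layer expression panels against a continuous
phenotype: per-layer differential expression with the exact filter
conventions of each platform, cross-layer candidate classification,
anti-correlated conserved-target overlap, coinertia analysis, and
hypergeometric overrepresentation. A synthetic-study generator plants known
regulators and targets so that the whole pipeline is verifiable by
recovery.

## The method

Clones are split into **fast** (mu >= 0.025 h^-1) and **slow**
(mu <= 0.023 h^-1) groups; rates in the open gap are excluded from group
tests. Then:

1. **miRNA (qPCR).** Ct values are normalised to a reference assay
   (dCt = Ct(miR) - Ct(ref)); the group fold change is `2^-ddCt` with
   ddCt = mean dCt(fast) - mean dCt(slow). A miRNA is DE when
   FC >= 1.2 in either direction with Benjamini-Hochberg adjusted
   p < 0.05 (Welch test on dCt). DE miRNAs whose expression-scale Pearson
   correlation with growth rate satisfies |PCC| >= 0.4 form the
   **priority set**, partitioned into up- and down-with-growth.
2. **mRNA (microarray).** Probesets must reach the detection threshold
   (log2 intensity >= log2(100) in at least one sample). Detected probesets
   are tested (Welch on log2, FC from group geometric means, BH across
   detected probesets; DE iff FC >= 1.2 and q < 0.05), then collapsed to
   non-redundant annotated genes keeping the highest-expressed probeset.
3. **Protein (label-free).** Peptide features are filtered (ANOVA
   p < 0.05, charge +1..+3, more than 3 isotopes, ion score >= 30);
   protein abundance per run is the sum of retained *unique* peptide
   abundances; runs are averaged to clone-level log2 abundances. DE
   requires >= 2 peptides matched, FC >= 1.2 in either direction and raw
   p < 0.05.
4. **Classification.** Every DE protein and gene-level DE mRNA gets one
   label. **Group A** (translational repression): protein DE,
   representative probeset detected, mRNA not DE. **Group B**: probeset
   undetected or absent from the chip, mRNA-only DE, or DE at both layers
   (protein direction is carried forward).
5. **Target overlap.** A priority miRNA and an A/B candidate are connected
   iff a *conserved* prediction links them and their directions are
   opposite (repression expectation); edges are ranked by ascending total
   context+ score and exported as a bipartite network.
6. **Coinertia.** For Group-A-linked targets, paired samples-by-targets
   mRNA and protein log2 matrices are column-centred and the
   cross-covariance `C = (1/n) X'Y` decomposed by SVD; singular values are
   the per-axis co-inertia, the RV coefficient
   `trace(Sxy Syx) / sqrt(trace(Sxx^2) trace(Syy^2))` summarises global
   concordance, and each target is drawn as an arrow from its normalised
   mRNA score to its protein score — long arrows mean post-transcriptional
   divergence.
7. **Enrichment.** DE lists are tested against GMT term sets with the
   one-sided hypergeometric upper tail and BH adjustment (an EASE-style
   discounted variant is available).

## Worked example

The `analysis/` scripts run the whole study end to end
(`Rscript analysis/01_simulate.R` through `04_cia_and_enrichment.R`),
writing tables under `results/`. In code:

```r
library(miromics)

bundle <- simulate_study(sim_config(seed = 101))
res    <- run_pipeline(bundle)
score_recovery(res, bundle$truth)
#>           layer n_true n_called n_recovered sensitivity fdr
#>  mirna_priority     16       16          16           1   0
#>         mrna_de      6        6           6           1   0
#>      protein_de     18       18          18           1   0
#>           edges     21       21          21           1   0
```

The simulated panel plants 16 growth-tracking miRNAs (10 up, 6 down) among
44 nulls, 12 translational-repression (Group A) targets and 9
mixed-evidence (Group B) targets; the pipeline recovers all 16 priority
miRNAs, all 21 planted regulator-target edges, and classifies 12 A + 9 B
candidates with no false edges. The coinertia stage on the 12
Group-A-linked targets reports RV = 0.188 — low global mRNA/protein
concordance, exactly what planted translational repression should produce
— and the enrichment stage flags the planted repression term in the DE
protein list (hypergeometric p = 1.5e-10, q = 5.8e-10).

Across 20 independent seeds at the default noise levels the mean planted-
edge sensitivity is 0.99 with a mean edge false-discovery fraction of 0.02
(`analysis/03_recovery_benchmark.R`).

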