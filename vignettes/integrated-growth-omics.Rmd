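---
title: "Integrated miRNA/mRNA/protein analysis of growth-rate variation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated miRNA/mRNA/protein analysis of growth-rate variation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miromics)
```

## The scientific setting

A panel of clonal cell lines derived from one parental pool can differ
substantially in specific growth rate while sharing genetic background and
culture history. When such a panel is profiled in parallel at the miRNA,
mRNA and protein layers, the combination of the three lets us separate two
modes of regulation that single-layer data confound: transcriptional
change (mRNA and protein move together) and post-transcriptional,
translational-level change (protein moves, mRNA does not). The latter is
the canonical footprint of repressive miRNA action, so candidates carrying
it can be cross-referenced against sequence-based target predictions of
miRNAs that themselves track growth — anti-correlation between regulator
and target being the expected sign pattern for repression.

This vignette documents the modelling decisions, parameters, and numerical
conventions behind each stage, and what the synthetic benchmark does and
does not demonstrate.

## Growth groups

The specific growth rate is computed from paired viable-density
measurements as $\mu = (\ln d_2 - \ln d_1)/(t_2 - t_1)$ (h$^{-1}$). Clones
with $\mu \ge 0.025$ h$^{-1}$ are *fast* and $\mu \le 0.023$ h$^{-1}$ are
*slow*, both inclusive; the open interval between the cutoffs is a
deliberate buffer — clones there are labelled unassigned and excluded from
group testing so the contrast is never diluted by borderline phenotypes.

## Per-layer differential expression

**Test choice.** All three layers use the Welch two-sample t-test on
per-sample values (dCt, log2 intensity, clone-level log2 protein
abundance). Welch is the conservative default when the two clone groups
cannot be assumed to share a variance, which is plausible for groups
defined by thresholding a continuous phenotype. Degenerate inputs are
resolved rather than fatal so that batch loops stay total: two constant
groups with equal means give p = 1; constant groups with different means
(complete separation) are scored with a small variance floor
(10^-8 times the squared scale), yielding an effectively zero p-value.

**miRNA.** Ct values are normalised to a single reference assay
(default `Mamm-U6`). "Undetermined" wells are treated as missing, not
imputed at the cycle ceiling, to avoid censoring bias; assays with fewer
than two finite values in either group are excluded and flagged. The fold
change is $2^{-\Delta\Delta Ct}$ with $\Delta\Delta Ct$ the difference of
group means of per-sample dCt (samples, not replicate pre-averages, are
the biological unit). BH adjustment runs across all tested assays jointly.
The growth correlation is reported on the expression scale ($-\Delta Ct$),
so a positive coefficient means expression rising with growth; the raw
dCt-scale value (its negative) is emitted alongside for transparency. The
priority filter $|PCC| \ge 0.4$ is inclusive at the boundary, as is the
fold-change threshold (FC $\ge$ 1.2 *or* FC $\le$ 1/1.2).

**mRNA.** Probesets must reach log2(100) intensity in at least one sample
(inclusive) to count as detected; BH adjustment is computed across
detected probesets only, matching the order of operations in which
undetected probesets never enter testing. Array fold change is the ratio
of group geometric means, i.e. $2$ to the difference of log2 means — the
standard convention for log-scale array data. Gene-level collapsing keeps,
per gene, the DE probeset with the highest mean expression over all
samples (ties broken by smallest probeset id, making the choice
deterministic); genes whose DE probesets disagree in direction are
flagged rather than silently resolved.

**Protein.** The peptide filter applies four criteria with their exact
boundary readings: feature ANOVA p strictly below 0.05, charge +1..+3
inclusive, isotope count strictly greater than 3, ion score at least 30
inclusive. The feature ANOVA p is accepted as an input column when the
upstream quantification software provides it and computed as a one-way
ANOVA across clone groups when absent. Rollup sums only *unique* peptides
— shared peptides contribute nothing, so column sums of the protein
matrix equal the retained unique-peptide mass per run. Replicate runs are
averaged to clone-level log2 abundances (pseudocount 1) before testing,
because clones, not injections, are the biological unit. Protein DE uses
the *raw* p-value — deliberately unlike the miRNA/mRNA layers — because
the protein criterion set pairs its p threshold with a harder gate
(>= 2 peptides matched); the BH-adjusted value is still reported. An
optional PCA-based outlier pre-step (samples beyond k = 4 MADs from the
centroid in the PC1-PC2 plane) is available but disabled by default, since
any such rule is a stand-in for case-by-case quality control.

## Candidate classification and target overlap

Candidate identity is the gene symbol, the natural join key between
protein identifications, probeset annotation and prediction tables. Every
DE protein and every gene-level DE mRNA receives exactly one label:

* **Group A** — protein DE, representative probeset detected, mRNA not
  DE: the translational-repression signature.
* **Group B** — (1) probeset below detection or absent from the chip
  (the two are distinguished in the recorded reason), (2) mRNA DE with no
  protein identified, (3) DE at both layers. Dual-DE candidates stay in
  clause 3 whether their directions agree or not, and the protein
  direction is the one carried into target overlap whenever protein
  evidence exists.

Overlap admits only conserved predictions and only anti-correlated pairs
(miRNA up with growth against down candidates and vice versa), ranking
edges within each miRNA by ascending total context+ score (more negative
= stronger predicted repression). Mature miRNA ids are matched to
family-keyed prediction tables by stripping the species prefix, any
trailing star marker and the -3p/-5p arm suffix; the mapping can be
overridden with an explicit table, since no single rule covers every
naming generation. Priority miRNAs absent from the prediction table are
logged and excluded rather than failing the run.

## Coinertia analysis

The two tables are samples-by-targets log2 matrices over the same sample
and target ordering, column-centred with uniform row weight $1/n$. The
cross-covariance $C = \frac{1}{n} X_c^\top Y_c$ is decomposed by SVD; the
$k$-th singular value is the co-inertia of axis pair $k$, and the first
pair maximises $\mathrm{cov}(X_c u, Y_c v)$ over unit vectors. A centred
("PCA-style") triplet with no column rescaling is used because the inputs
are signed log-scale expression values, for which a chi-square triplet
would be inappropriate; column standardisation is available as a switch.
Target scores are the singular vectors scaled by $\sqrt{\lambda}$
(symmetric scaling). Axis sign indeterminacy is resolved by making the
largest-magnitude mRNA loading on each axis positive and flipping the
paired protein axis with it, so repeated runs are bit-identical. For the
arrow plot, the mRNA and protein score sets are independently rescaled to
unit maximum norm; the arrow length (base-to-head distance) is the
per-target mRNA/protein divergence, reported sorted descending. The RV
coefficient uses the standard trace form and is exactly 1 for $Y = cX$,
$c > 0$. Self-coinertia of a table recovers its PCA eigenvalues, which
the tests verify to 10^-8 relative error.

## Enrichment

Overrepresentation is the one-sided hypergeometric upper tail per term,
BH-adjusted across terms. The universe defaults to the annotated genes on
the expression platform and is always explicit, because background choice
is the classic pitfall of enrichment tools. An EASE-style variant (one
observed hit discounted; single-hit terms score p = 1) is one flag away
for users comparing against DAVID-era results.

## The synthetic study

The generator's defaults are the study conditions, not tuning knobs:
30 clones spanning 0.011-0.044 h$^{-1}$, 15 fast and 15 slow drawn
uniformly within their group ranges; 3 proteomic replicate runs per clone;
16 planted regulator miRNAs (10 up, 6 down) among 44 nulls; 12 Group-A
targets and 9 Group-B targets (cycled over the three B patterns) among
120 null genes. The planted Ct slope is 40 cycles per unit growth rate,
which at the realised group separation yields roughly a 1.6-fold miRNA
group fold change; planted mRNA and protein log2 effects are 0.5 (about
1.4-fold). Noise is Gaussian on Ct (sd 0.2 cycles), Gaussian on log2
array intensity (sd 0.2) and log-normal on peptide abundance (sd 0.15 on
log2) — the standard noise family for each platform. Where the emulated
design did not state a value (noise sds, baseline ranges, decoy rate),
values were chosen once as field-plausible and are not revisited.

Two design points matter for what the benchmark proves. First,
regulator-target coupling acts on the regulator's *realised expression*,
not on the group label, so the growth-correlation filter and the
anti-correlation rule are genuinely exercised rather than trivially
satisfied. The coupling coefficient is calibrated per seed so the planted
group effect equals the configured log2 effect at the realised regulator
separation. Second, the peptide table deliberately contains shared
peptides and peptides failing each single filter criterion, so the rollup
and filter branches are all exercised on every run.

What the generator does *not* emulate: probe-level array artefacts and
normalisation, amplification-efficiency differences between qPCR assays,
retention-time alignment and missingness structure of real LC-MS data,
correlated (clustered) miRNA families, and annotation ambiguity across
species. Passing recovery tests therefore demonstrates the correctness of
the statistical pipeline under its stated model, not robustness to every
failure mode of the upstream platforms.

Problem sizes in the tests and benchmark scripts (30 clones, ~60 assays,
~160 probesets, ~235 peptide rows over 90 runs; 20-seed replication) were
chosen so a full simulate-and-recover cycle takes a couple of seconds,
which is the scale at which property-style testing over many seeds is
practical.

## Determinism and degenerate inputs

Every stochastic step lives in the generator behind a single mandatory
seed; the pipeline itself is a pure function of its inputs, and all
serialisation uses one fixed TSV convention, so reruns are byte-identical
(hash-verified in the tests). Degenerate cases have defined behaviour
throughout: constant assays are excluded from correlation with a flag,
zero-variance group pairs resolve to p = 1 or complete separation as
described above, a constant peptide feature scores ANOVA p = 1 (no
signal) while a between-group-only split scores 0, and empty stage
outputs (no DE calls, no priority miRNAs, no linked targets) propagate as
empty tables rather than errors — a coinertia stage without usable
targets or with a zero-inertia table is skipped with a note.

## Known limitations

* Group labels discretise a continuous phenotype; the correlation filter
  partially compensates, but a fully continuous model (e.g. regression on
  growth rate at every layer) is out of scope.
* No moderated-variance (empirical Bayes) testing; with small panels the
  Welch test is noisier than shrinkage-based alternatives.
* Only one reference assay is supported for qPCR normalisation
  (no multi-reference geometric means).
* The mRNA/protein join assumes consistent gene symbols across platforms;
  real cross-species annotation requires curation the package does not
  attempt.
* The enrichment module does not propagate term hierarchies; terms are
  tested as flat sets.
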