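---
title: "Methods: multi-omics integration, network propagation and downstream statistics"
author: "omicwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics integration, network propagation and downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicwalk)
```

## Overview

`omicwalk` implements an integrative strategy for prioritizing cancer genes
from paired tumor/normal cohorts. The reasoning behind it is that
transcriptional dysregulation is most credible as a driver event when it is
accompanied by a *consistent* upstream lesion — a copy-number change, a
promoter methylation change, or recurrent somatic mutation — and that the
joint influence of many such genes is best read off a molecular interaction
network rather than gene by gene. The pipeline has four stages:

1. **Per-layer differential testing.** Paired t tests per gene on
   tumor − normal differences, separately for expression, gene-level copy
   number and promoter methylation, each followed by Benjamini–Hochberg
   false-discovery-rate control; mutation data are screened by per-gene
   mutation frequency.
2. **Integration.** Differentially expressed genes (DEGs) are classified
   into three groups by upstream consistency, and each gene receives a
   source score 0–3 equal to the number of groups it belongs to.
3. **Network propagation.** DEGs are projected onto a merged interaction
   network; the biggest connected component becomes the walking graph; a
   random walk with restart started from the score-weighted source
   distribution yields a steady-state probability per gene, whose
   significance is assessed by node-label permutation.
4. **Downstream statistics.** Kaplan–Meier curves, log-rank tests,
   univariate Cox regression and chi-squared association tables for the
   clinical follow-up.

## The differential layer

For a gene with paired differences $d_i = x^{tumor}_i - x^{normal}_i$,
$i = 1..n$, the statistic is $t = \bar d / (s_d/\sqrt n)$ on $n-1$ degrees
of freedom, two-sided. Genes whose differences are constant
($s_d = 0$, e.g. all-zero rows) are flagged untested rather than assigned a
degenerate p-value, and excluded from significance calling; the same holds
for rows with missing values. FDR control is Benjamini–Hochberg
(`stats::p.adjust`); the procedure is not named in most clinical reports but
BH is the field default for TCGA-style screens. Default thresholds follow
common practice for this design: expression FDR < 0.01, copy number
FDR < 1e-5, methylation FDR < 0.01, mutation rate ≥ 5%. The copy-number
threshold is unusually strict; it is kept as the default deliberately and is
configurable.

Copy-number input is a segmentation table (log2 ratios from circular binary
segmentation — segmentation itself is an input, never recomputed). The
gene-level value in a sample is the overlap-length-weighted mean of all
segments overlapping the gene body, with 1-based closed coordinates on both
sides; a gene with no covered base is missing in that sample. The weighted
mean was chosen over cruder rules (e.g. the segment containing the gene
midpoint) because it is exact under the per-bp averaging definition — the
test suite checks agreement with a literal per-base-pair oracle.

Promoter methylation uses the conventional promoter window: 1000 bp
upstream of the transcription start site to 300 bp downstream, strand-aware
and clamped at position 1 (whether public pipelines clamp at chromosome
ends is rarely stated; clamping is the safe choice). A gene's methylation
level per sample is the mean β of all probes falling in the window —
boundary positions included (closed interval), probe strand ignored since
array probes interrogate a locus, not a strand. Genes without any promoter
probe are absent from the methylation layer, and so can never join the
methylation group. Tests are run on β values directly, as is usual when the
upstream platform reports β.

SGOL (Segment Gain Or Loss) summaries use per-gene thresholded sums across
samples (gain: sum of values above +0.2; loss: sum below −0.2; thresholds
configurable), with sex chromosomes excluded so mixed-sex cohorts do not
inject dosage artefacts.

## Integration into groups and scores

Group membership is gated on DEG status and on direction consistency:

* **Group A** — DEG with consistent copy number: up-regulated & amplified,
  or down-regulated & deleted.
* **Group B** — DEG with consistent promoter methylation: up-regulated &
  hypomethylated, or down-regulated & hypermethylated.
* **Group C** — DEG with mutation frequency ≥ 5% (no direction requirement;
  mutations can act in either direction).

The DEG gate is strict: a gene significant in an upstream layer but not
differentially expressed joins nothing. The source score is the number of
group memberships (0–3); genes with score 0 are information *targets*.
Two structural properties are tested: scores partition the gene universe,
and removing a layer can only lower or preserve scores.

## Random walk with restart

With $W$ the column-normalized adjacency matrix of the walking graph and
$p^0$ the restart distribution (source scores normalized to sum 1), the
walk iterates

$$p^{t+1} = (1-r)\,W p^t + r\,p^0$$

until the L1 distance between successive iterates falls below $10^{-10}$.
The restart probability defaults to $r = 0.7$, a strongly local setting
appropriate when source annotations are trusted: the walker stays within a
short radius of the sources. Because the iteration is a contraction with
factor $(1-r)$, the gap shrinks geometrically and convergence to $10^{-10}$
takes about 20 iterations at the default; probability mass
$\sum_i p^t_i = 1$ is asserted at every step. An independent dense linear
solve of the fixed point, $p = r\,(I-(1-r)W)^{-1}p^0$, is provided as an
oracle and the two routes are required to agree below $10^{-8}$ in
L-infinity in the tests.

The walking graph is built by merging edge lists (direction dropped,
self-loops removed, duplicate undirected edges collapsed), inducing the
subgraph on the DEG set, and keeping the biggest connected component (ties
broken toward the component containing the lexicographically smallest
node). Building $W$ on the component only guarantees no dangling zero-degree
columns.

### Permutation significance

Significance of a gene's steady-state probability is empirical: the score
vector is shuffled over the nodes (topology fixed, score multiset
preserved) `n_perm` times (default 10,000; scaled runs use 500), the walk
is re-run per shuffle, and the per-node p-value is the upper-tail fraction
with an add-one pseudo-count,

$$p_{perm} = \frac{1 + \#\{\text{permutations with } p^{\infty}_{perm} \ge p^{\infty}_{obs}\}}{n_{perm}+1},$$

so p-values are never exactly zero and are valid (super-uniform) under the
null by exchangeability. Two design choices deserve a note. First, the
upper tail is the scientifically meaningful one — the aim is to flag genes
with significantly *high* steady-state probability — and is what this
package computes. Second, the null is node-resolved: each node is compared
with its own permutation distribution, since label permutation on fixed
topology naturally yields per-node nulls (high-degree nodes have higher
typical steady-state mass, and a pooled null would confound degree with
signal). Genes with $p_{perm} < 0.02$ (strict) are reported as
significantly afflicted. Permutations are drawn from a seeded stream, so
runs are exactly reproducible; results are independent of the internal
batching size because the draw order is fixed.

## Survival and association statistics

Patients are dichotomized at the marker median, ties assigned to the low
group (the convention is rarely stated in clinical reports; ties-low keeps
the high group strictly above the median). Group survival is compared with
the standard one-degree-of-freedom log-rank statistic (implemented
directly from the O−E/V tabulation and cross-checked against
`survival::survdiff`), Kaplan–Meier curves come from `survival::survfit`,
and hazard ratios from a univariate Cox model
(`survival::coxph`, Efron tie handling — the standard default; Wald 95%
intervals and p-values to match the usual table layout). Monotone
likelihood (a covariate level with no events) and constant covariates are
explicit errors, never silent extreme estimates.

Baseline-characteristics tables are tested with Pearson's chi-squared,
applying the Yates continuity correction exactly when the table is 2×2.
This convention reproduces the printed p-values of the bundled published
cohort (`lusc_ihc_tables()`, 102 male LUSC patients stratified by ERα
immunohistochemistry) to within 0.001; the uncorrected 2×2 values differ
markedly (e.g. 0.154 vs 0.246 for the age table), which is how the
convention was identified. A Fisher-exact mode is available. The pN row of
the source table is garbled in the original and is omitted.

## The synthetic cohort generator

Real cohorts of this design cannot be bundled, so `generate_cohort()`
produces seeded cohorts with the statistical structure the analysis
assumes, at about one-third of the motivating study's scale: 17 expression
pairs, 79 copy-number pairs, 13 methylation pairs and 183 mutation
patients over 300 genes on 4 chromosomes (the original cohorts were
51/237/40/548 over genome scale). These sizes keep the full test suite and
acceptance run within minutes while leaving every stage statistically
non-trivial.

The generator plants:

* **DE genes** (default 10% of genes, half up, half down) as an additive
  tumor − normal shift (default +10 units, Gaussian noise SD 3) on
  log-normal per-gene baselines; raw counts are the rounded values.
* **Consistent lesions** among the DE genes with the layer proportions of
  the motivating cohort — about 28% copy-number-consistent, 20%
  methylation-consistent and 4.5% mutation-frequent — so the score
  multiset is realistic: most sources score 1, few score 2, very few 3.
* **Copy number** as per-sample segment tables (so the segment→gene mapping
  is genuinely exercised); planted genes are isolated in their own tumor
  segment carrying ±0.5 in log2 ratio.
* **Methylation** as a probe table with 0–6 probes per promoter (≥1 for
  planted genes, so both the mean-aggregation and missing-probe paths are
  hit), with hypomethylation planted under up-genes and hypermethylation
  under down-genes (β shift 0.25 within the clamp-safe baseline range).
* **A scale-free network** grown by preferential attachment from a hub seed
  set; hub genes are planted as high-score sources (lesions in both the
  copy-number and methylation layers) and the remaining source genes are
  preferentially wired to them, so propagated information converges at
  hubs — the structure the walk is designed to detect.
* **Clinical data** with exponential event times whose hazard is multiplied
  by $e^{\beta x}$ for a balanced binary covariate (default β = 0.7) and
  independent exponential censoring calibrated to the requested censoring
  fraction — the simplest model satisfying the proportional-hazards
  assumption the Cox stage fits.

All randomness flows from one explicit seed through per-layer child seeds;
the global RNG state is saved and restored, and identical configurations
serialize bit-identically.

What the generator does **not** emulate: realistic allele frequencies or
mutation signatures, spatial autocorrelation of methylation, count-based
expression noise (mean–variance coupling), overlapping genes, or
non-proportional hazards. Passing recovery tests therefore demonstrate the
pipeline's correctness and calibration under its own assumptions, not
performance on real cohorts; on real data, effect sizes are smaller and the
error control rests on the same guarantees but with lower power.

## Numerical and reproducibility choices

* Coordinates are 1-based closed everywhere; SEG input is read as 1-based
  inclusive.
* Convergence is measured in L1 with tolerance $10^{-10}$; exceeding the
  iteration cap raises an error carrying the last gap rather than returning
  a stale vector.
* Empirical p-values use the add-one pseudo-count; significance thresholds
  are strict inequalities at every stage.
* The pipeline writes only plain TSV/JSON stage outputs, and its manifest
  records configuration, per-stage record counts and output-file hashes;
  manifests contain no wall-clock fields, so identical seeds yield
  identical manifests.
* Scaled runs used throughout the tests: 300-gene cohorts, networks of
  100–300 nodes, 500 permutations, 20 simulation seeds.

## Limitations

The group definitions inherit the classical cis-regulation reading of copy
number and promoter methylation; trans effects are out of scope. The
permutation null preserves topology and the score multiset but not any
covariance between scores and degree that a real cohort might carry.
Multivariable Cox modeling, competing risks, probe-level methylation
normalization and enrichment analysis of the resulting gene sets are
deliberately outside the package.
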