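---
title: "Inferring a regulator-driven root meristem network: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a regulator-driven root meristem network: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramnet)
```

## Overview

`ramnet` reconstructs a transcription-factor-driven gene regulatory network
for the root apical meristem (RAM) from four kinds of evidence and then
qualifies it in two further ways:

1. **Zone-specific differential expression.** Bulk RNA-seq of the
   meristematic (MZ), elongation (EZ) and differentiation (DZ) zones, three
   replicates each, yields the *meristem-specific* gene set: genes called up
   in MZ against both EZ and DZ.
2. **Induction response.** Per-regulator lists of genes that respond to
   transient activation of the regulator.
3. **Promoter motif presence.** Genes whose upstream region carries a
   binding site of one of the regulators, found by scanning position weight
   matrices (PWMs) against an order-2 Markov background.
4. **Network assembly.** A gene is a putative direct target when all three
   lines of evidence agree; edges connect each regulator to the targets its
   induction list (and, optionally, its own motif) supports.
5. **Co-expression context.** A weighted co-expression network over the
   meristem genes (soft-thresholded correlation, topological overlap,
   module detection, eigengenes) and a permutation Z-summary that asks
   whether modules are preserved in a second species' data mapped through
   bidirectional best hits (BBH).
6. **Cell-type weighting.** Single-cell expression gives each gene an
   activity in [0, 1] per cell type; edges are weighted by the geometric
   mean of their endpoint activities, and a two-component Gaussian mixture
   per cell type separates weak from retained interactions at the posterior
   0.5 crossing.

Every stage can be exercised on synthetic data with known ground truth; the
generators live in the package and are pure functions of a seed.

## Differential expression

Counts are filtered to genes with more than 1 count per million in at least
3 of the 9 samples, then normalized with median-of-ratios size factors
(reference genes are the rows with strictly positive counts everywhere,
because the geometric mean is undefined with zeros). The test is a per-gene
two-group negative-binomial GLM with log link and size-factor offsets, fit
exactly by Newton iteration, with variance function Var = mu + alpha mu^2.

The null hypothesis is composite: |log2FC| <= 1 by default. The Wald
statistic is (|log2FC| - 1) / se, its one-sided tail doubled, and p clamped
to 1 whenever the estimate lies inside the null region — the standard
conservative treatment of a threshold null. Benjamini-Hochberg adjustment
runs over the tested genes.

Three numerical choices matter at three replicates per zone:

* **Dispersion pooling.** The gene-wise method-of-moments estimator pools
  within-zone residuals, so genes with real zone effects do not inflate
  their own dispersion. With 6 observations it is still far too noisy to
  plug in per gene: underestimates inflate the type-I error (we measured
  ~12% at nominal 5%) and overestimates cost power. The test therefore uses
  the across-gene median for every gene. This matches the synthetic data,
  where dispersion is shared across genes by construction; for real data
  with strongly gene-specific dispersion and more replicates, pass explicit
  per-gene `dispersions`.
* **Small-sample correction.** The Wald standard error carries the
  residual-degrees-of-freedom factor sqrt(n / (n - 2)) for the n samples of
  the contrast. Measured on null simulations (2,000 genes, dispersion 0.1,
  3v3) the empirical type-I error at nominal 5% is 0.03-0.05, and
  sensitivity for planted log2FC = 3 effects at baseMean >= 100 is >= 0.9.
* **Normalization assumption.** Median-of-ratios assumes most genes are not
  differential. The default simulation plants 15% meristem-specific genes;
  pushing that fraction toward 1/3 visibly biases fold-change estimates
  downward. This is a property of the normalization, not of the
  implementation.

`vst()` is log2(normalized count + 1), a simple homoscedasticity-improving
transform used for the co-expression stage.

## Promoter extraction and motif scanning

Promoters are the 3,000 bp upstream of the TSS (1-based inclusive
coordinates throughout; BED input is converted on read). With `noorf` the
window is truncated at the nearest boundary of any other gene's span that
overlaps it, and windows are clipped at chromosome ends; minus-strand genes
use the reverse complement of the downstream interval. The synthetic genome
always lays out at least one gene pair closer than the window so the
truncation branch is exercised by every end-to-end run.

Scanning scores each window in nats as the log-probability of the window
under the PWM minus its log-probability under an order-2 Markov background
trained on both strands of the genome (trinucleotide counts, pseudocount 1).
The first two positions of a window use the stationary dinucleotide
distribution, the rest the conditional p(base | two-base context).

p-values come from an exact dynamic programme: per-column log-odds
contributions against the *order-0 marginal* of the background are
discretized to 1e-3 nats and convolved, giving the full null score
distribution. Using the order-0 null for calibration while scoring against
the order-2 background is a deliberate simplification — an exact order-2
null would need context-coupled DP — and it is oracle-tested against
exhaustive enumeration. To keep the false-positive calibration property
exact, the default synthetic background is AT-rich (A = T = 0.3,
C = G = 0.2) but context-independent; a context-dependent conditional table
can be supplied to study the mismatch.

The per-hit threshold defaults to p <= 1e-4 and is exposed, since no
universal convention exists; gene-level motif presence is an existence test
over both strands. Generated motifs are width 12 with 0.95 of each column's
mass on the consensus: planted instances are sampled column-wise (not
consensus-only), and at this informativeness ~98% of sampled instances
still clear the default threshold, so planted-motif recovery is a sharp
benchmark rather than a coin flip.

## Co-expression, modules, preservation

Correlation is Pearson or biweight midcorrelation (bicor); bicor weights
observations by (1 - u^2)^2 with u = (x - median) / (9 MAD) and falls back
to Pearson standardization for zero-MAD genes, recording them. Adjacency is
|cor|^beta (unsigned by default; signed available). The soft threshold beta
is chosen as the smallest power whose binned log-log degree distribution
fits a line with signed R^2 >= 0.8; if none qualifies the argmax is taken
and flagged. Note that independent noise also attains high fit indices at
large powers while mean connectivity collapses — the fit index alone does
not certify modular structure.

Topological overlap is TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij),
checked against a cubic triple-loop oracle to 1e-12. Modules come from
average-linkage clustering of 1 - TOM with a *static* cut: the cut height
defaults to the midpoint of the largest gap between consecutive sorted
merge heights, searched above their median. A fixed quantile of the heights
was tried first and rejected — it always isolates a fixed number of top
merges, regardless of how many modules the data actually contain — while
the largest-gap rule recovers planted modules (adjusted Rand index ~1 on
4 planted modules at 9 samples) and leaves independent genes mostly
unassigned. Clusters below 30 genes are unassigned (label 0); labels are
ordered by decreasing size. The dynamic tree cut used by the reference
implementation is intentionally out of scope: it is an algorithm of its
own, and a deterministic cut is testable.

Module eigengenes are the per-sample first principal component of the
z-scored module submatrix, unit variance, sign-oriented so the mean member
correlation is non-negative; kME is each gene's correlation with each
eigengene.

**Preservation.** For each reference module the test data yields an
observed density (mean off-diagonal intramodular adjacency) and an observed
connectivity (correlation of intramodular connectivity between reference
and test over the module's genes). Both are compared against 200 random
same-size gene sets — "200 interactions" in the source protocol is read as
200 permutations — giving Z_density and Z_connectivity;
Z_summary is their mean. Values above 2 are read as evidence of
preservation, above 10 as strong evidence. Unlabeled genes stay in the
permutation background; each module draws its permutations from a stream
seeded by its own gene content, which makes the Z values invariant to
module numbering. Preservation uses bicor by default, matching the source
protocol. The generator plants module structure with mutually orthogonal
latent factors: with only 9-12 samples, unconstrained random factors
correlate strongly with each other and would blur "distinct modules" into
one another before any method sees the data.

## Network assembly and conservation

Targets are the triple intersection meristem x induced x motif-bearing. The
motif condition defaults to *any* regulator's motif (`motif_mode = "any"`),
because the filter in the source protocol is the presence of a binding
motif, not a regulator-matched one; `"matched"` mode is provided because
the regulators' PWMs are near-identical in practice and the distinction is
visible on synthetic data. Edges connect regulator r to target g when g is
in r's induction set (and, under `"matched"`, carries r's motif);
regulators remain nodes even when edgeless.

BBH orthology takes the best hit per query by bitscore, ties broken by
smaller e-value then lexicographic subject id, and flags mutual best pairs;
the per-species networks are mapped to reference gene ids and the nodes on
the `top_k = 100` lowest-variance shared edges are reported (ties by edge
id). Enrichment is an upper-tail hypergeometric test per term with BH
adjustment and p/q thresholds of 0.05/0.01.

## Single-cell activity and mixture thresholding

Gene activity per cell type is the per-type mean of log1p library-size
normalized expression, z-scored across types per gene and min-max rescaled
to [0, 1]; zero-variance genes get 0 and a flag, and types with fewer than
10 cells are excluded. The exact normalization of the original single-cell
framework is not fully specified in the source protocol, so this scaled
summary is a documented stand-in with the same interface. Edge weight in a
cell type is sqrt(a_i a_j): symmetric, in [0, 1], and zero when either
endpoint is inactive (arithmetic mean and minimum are available for
sensitivity analysis).

The weight distribution per cell type is decomposed into two Gaussians by
EM (k-means initialization under an explicit seed, at most 1,000
iterations, tolerance 1e-8, components ordered mu1 < mu2; a degenerate
component triggers one jittered restart). Edges whose posterior probability
of the lower-mean component exceeds 0.5 are weak and discarded; the
threshold is the smallest posterior-0.5 crossing in [mu1, mu2], solved in
closed form from the quadratic the equality defines. Two guards matter:

* **No separation** (|mu2 - mu1| < 2 max(sigma)): a unimodal distribution
  must not silently lose half its edges; everything is kept and flagged.
* **Degenerate distributions**: an all-zero activity column retains nothing,
  while a uniformly active type keeps its positive-weight edges, flagged.

On the planted mixture 0.5 N(0.3, 0.05^2) + 0.5 N(0.8, 0.05^2) the fit
recovers both means within 0.02 and the threshold lands at 0.55 +- 0.02;
for a symmetric mixture the crossing is exactly the midpoint.

## The synthetic benchmark

The default configuration (`sim_config`) is the package's study condition:
2,000 genes, 4 regulators, 300 planted meristem genes containing 150 true
targets, zone log2 effect 3, NB dispersion 0.1, mild log-normal depth
variation, full motif planting, 10% induction noise drawn from non-meristem
genes (so noise does not masquerade as signal), 5 cell types x 60 cells
with the first type elevated by 2 log units for regulators and targets, 3
species at 80% ortholog conservation. A second species' counts are
generated from the same truth and reached through simulated BLAST-like hit
tables via BBH, so the preservation stage runs end to end.

What the generators do *not* emulate: UMI sampling and dropout in the
single-cell data (log-normal only), per-gene dispersion variation (alpha is
shared), genome-scale sequence composition beyond a stationary AT-rich
background, unbalanced designs, and batch effects. Passing benchmarks here
demonstrates the machinery is correct under its stated model, not that real
accessions would reproduce any particular published gene count — those
depend on the original accessions and tools throughout.

Problem sizes used by the test-suite benchmarks: 2,000-gene null and
recovery simulations for the DE calibration (5 seeds, medians), all 4^6
hexamers for exact scan scoring, 4^5 enumeration for DP p-values, 50-gene
random adjacencies against the TOM oracle, 200-gene/4-module/9-sample
module recovery, 300-gene preservation with 200 permutations, 5,000-point
mixtures, and one full default-size pipeline run (about 1.5 minutes on one
CPU).

## Reproducibility

Every stochastic operation takes an explicit seed; pipeline stages derive
theirs as global seed plus fixed offsets, so changing one stage's draw
cannot ripple into others. Two runs with the same configuration are
checksum-identical, which the test suite asserts. `scripts/acceptance.R`
recomputes the headline quantities from scratch for any seed.
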