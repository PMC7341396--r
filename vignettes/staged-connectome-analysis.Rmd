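---
title: "Staged connectome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged connectome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

`stagenet` studies how the topology of the resting-state functional
connectome changes across the ordered disease stages NC → EMCI → LMCI → AD.
Each subject contributes a T × N matrix of ROI time series (by default
T = 130 volumes, N = 90 atlas regions).  Pearson correlation gives an N × N
connectivity matrix; thresholding it at a sweep of edge densities
("sparsities") S gives a family of binary graphs, on which five global
metrics are computed: characteristic path length (Char), global efficiency
(Effi), clustering coefficient (Clus), transitivity (Tran) and
small-worldness (SW).  Each metric's curve over the sweep is summarized by
its area under the curve (AUC), removing the dependence on any single
threshold.  The same machinery runs on six resting-state subnetworks (DMN,
ATT, SUB, AUD, VIS, SEN).  Groups are compared with nonparametric
permutation tests (metric AUCs) and Welch t-tests (edge weights,
inter-network connectivity), each family corrected by Benjamini–Hochberg
FDR.  Finally, each subnetwork's (metric, stage) trajectory of group-mean
AUCs is classified as a *temperature inversion* (rise to a peak at EMCI,
then decline), a *monotonous decline*, a U-shape, or neither, and
subnetworks sharing a majority pattern are grouped into homogeneous evolving
sets.

# Graph metrics

For a binary undirected graph with N nodes, hop distances $d_{ij}$, degrees
$k_i$ and per-node triangle counts $t_i$:

* $\mathrm{Char} = \frac{2}{N(N-1)} \sum_{i>j} d_{ij}$ (mean hops over pairs),
* $\mathrm{Effi} = \frac{1}{N(N-1)} \sum_{i \ne j} 1/d_{ij}$ with $1/\infty = 0$,
* $\mathrm{Clus} = \frac{1}{N}\sum_i C_i$, $C_i = t_i / \binom{k_i}{2}$ and
  $C_i = 0$ for $k_i < 2$,
* $\mathrm{Tran} = \sum_i 2 t_i \big/ \sum_i k_i (k_i - 1)$,
* $\mathrm{SW} = (C/C_0) / (L/L_0)$, where $C_0, L_0$ are ensemble means of
  clustering and path length over 100 uniform random graphs with the same
  node and edge count.

All five are implemented directly (distances by repeated boolean matrix
products, triangles via $\operatorname{diag}(A^3)/2$) and verified in the
test suite against exhaustive brute-force oracles (Floyd–Warshall,
triple/triangle enumeration) and against igraph.

**Disconnected graphs.** At low sparsity binary graphs fragment and the
plain Char formula is infinite.  Char therefore averages over *reachable*
pairs only and every result carries a `connected` flag; Effi needs no
special case.  Nodes of degree 0/1 contribute $C_i = 0$.  Empty subnetwork
graphs (an edge budget of zero) are flagged and excluded from that curve's
AUC segment, so the AUC is taken over the valid sub-grid.

**Numerical conventions.** The edge budget at sparsity S is
$k = \lfloor S\,N(N-1)/2 + 0.5\rfloor$ (round-half-up), making densities
bit-reproducible.  Edges are ranked by *signed* correlation (strongest
positive first), the usual convention in sparsity-threshold studies of
correlation networks; ranking by magnitude is available via `rank =
"absolute"`.  Ties at the cutoff are broken by lexicographic (i, j)
position — deterministic and seed-free — which also makes binarization
monotone: the edge set at a lower sparsity is a subset of the edge set at a
higher one.  No Fisher transform is applied before binarization (it is
rank-preserving); Fisher z *is* applied to edge weights before t-tests.

# The sparsity sweep

The default sweep is S ∈ [0.08, 0.52] in steps of 0.01 (45 densities).
With `auto_sparsity = TRUE` the range is re-derived from the control group
as the maximal contiguous run of candidate sparsities where (a) the mean
degree of every NC graph is at least $2\log N$ and (b) the NC group-mean
small-worldness is at least 1.1.  Because the edge budget is a function of
(N, S) alone, criterion (a) is deterministic and reduces to the closed form
$S \ge 2\log N/(N-1)$ (≈ 0.101 for N = 90) in the continuous approximation.
"log" is the *natural* logarithm by default: for N = 90 that yields a mean
degree floor of ≈ 9.0 and a lower bound adjacent to the adopted sweep start,
whereas log10 would give an implausibly small floor (≈ 3.9); a `log_base`
switch exposes the alternative.  Criterion (a) is applied per subject
(trivially, since it is degree-deterministic) and criterion (b) to the group
mean; both readings are documented here because the choice is not forced by
the formulas.

# Subnetwork analysis

Two constructions of a subnetwork's binary graph are supported:

* `"global_restrict"` (default): threshold the whole-brain matrix at S, then
  restrict the binary graph to the subnetwork's ROIs.  A subnetwork's edge
  count then reflects how strongly its regions couple *relative to the rest
  of the brain*, which is exactly the quantity that differs across stages
  when within-network coupling strengthens or weakens.
* `"own_budget"`: threshold the subnetwork's own correlation block with its
  own budget $k = \lfloor S\,|n|(|n|-1)/2 + 0.5\rfloor$, fixing every
  subnetwork's density to the sweep value.

The default matters.  When stage effects act on the *level* of
within-network correlation (as in the synthetic generator, and as implied by
a block-structured connectome), own-budget thresholding discards nearly all
of the signal: a uniformly coupled block thresholded at its own budget is
close to an Erdős–Rényi graph whatever the coupling level, so its metrics
barely move across stages.  Restriction of the global graph retains the
signal in the subgraph's density and is also the construction suggested by
writing the subnetwork binary matrix as entries $b^n_{ij}$ of the global
binary matrix.

**Subnetwork small-world reference.** For restricted subgraphs the reference
density is ambiguous: matching the subgraph's *realized* edge count
normalizes away precisely the density differences that carry the stage
effect (and in simulation slightly inverts the SW trajectories), while
matching the subnetwork's size at the *nominal sweep density* keeps the
reference a fixed function of the grid and leaves SW on the same footing as
the other four metrics.  The default is the sweep-density match
(`sw_ref = "sweep"`); `"realized"` is available for pure
topology-beyond-density questions.

Inter-network connectivity is the plain mean correlation over all ROI pairs
spanning two networks; the block means refine the global off-diagonal mean
exactly (a tested invariant).

# Group inference

* **Metric AUCs** (global and subnetwork): permutation test on the mean
  difference, 10,000 relabelings by default, with the add-one correction
  $p = (1 + \#\{\text{null at least as extreme}\})/(B+1)$ so p is never 0.
  One permutation stream is shared across the features of a family (the
  relabeling permutes subjects, not features).  The default is two-tailed:
  a one-tailed variant directional on the observed sign is provided
  (`tail = "one_tailed"`), but choosing the direction from the data doubles
  its type-I rate (measured ≈ 0.10 at a nominal 0.05 in the calibration
  suite), so the directional mode should only be used with a prespecified
  direction; BH-FDR also presumes valid p-values, which settles the default.
* **Edge weights**: Welch (unequal-variance) two-sample t-tests on Fisher
  z-transformed correlations — group sizes differ, so the pooled-variance
  test would be anticonservative.  A permutation alternative
  (`edge_method = "permutation"`, default 1,000 relabelings) is provided.
* **FDR families**: one BH family per contrast per analysis level (5 global
  metrics; all N(N−1)/2 edges; 30 subnetwork features; 15 network pairs) —
  the most conservative reading when family boundaries are not specified.
* **MMSE**: Pearson correlations of per-stage property values with MMSE
  scores, two-sided p from the t-distribution with n − 2 df.

All six pairwise stage contrasts are computed at every level; a contrast
with fewer than two subjects in a group is skipped with a warning.

# Trajectory classification

For each (subnetwork, metric), the four stage means of the AUC are
classified (see `classify_pattern()`):

* *temperature inversion*: a rise beyond `tol` from NC to a peak at EMCI,
  then a decline in which each step may reverse by at most `tol`;
* *monotonous decline*: every step downward within `tol` slack and a net
  NC→AD fall beyond `tol`;
* *U-shape*: interior minimum with falls into and rises out of it beyond
  `tol`; otherwise *other*.

The default tolerance is noise-scaled, `0.25 ×` the pooled standard error of
the stage means, which turns a by-eye judgement into a reproducible rule;
an absolute tolerance can be supplied instead.  The rule is this package's
own quantification — no canonical criterion exists for separating an
inversion from noise.

Because Char falls when connectivity strengthens, classifying its raw
trajectory would systematically mirror the other metrics.  The
classification therefore applies a fixed orientation (−1 for Char, +1
otherwise, `metric_orientation()`) before labeling, so "inversion" always
means "function rises then falls".  A network's overall pattern is the
majority label across its five metrics (ties → other), and networks sharing
a pattern form one homogeneous evolving group.

# The synthetic cohort generator

The generator emulates the statistical structure the analysis consumes, not
raw fMRI: zero-mean multivariate Gaussian time series whose block
correlation encodes the stage effects.  Defaults are the study conditions:
90 ROIs, 130 time points, group sizes NC 35 / EMCI 37 / LMCI 33 / AD 25,
MMSE means ± SD of 28.89 ± 1.21, 28.08 ± 1.74, 27.85 ± 1.64 and 22.72 ± 2.41
(drawn Gaussian, rounded — MMSE is an integer score — and clipped to
[0, 30]).  Within-network correlation trajectories across (NC, EMCI, LMCI,
AD) are (0.30, 0.45, 0.35, 0.20) for the four inversion-tagged networks
(AUD, DMN, VIS, SUB) and (0.45, 0.38, 0.30, 0.22) for the two decline-tagged
ones (SEN, ATT); these orderings are validated at configuration time, with a
`"none"` tag available for null cohorts.  The baseline between-network
correlation is 0.10 — weak but nonzero coupling, as is realistic for
resting-state data.  The implied covariance is checked for positive
definiteness (and repaired via `Matrix::nearPD()` with a flag if ever
needed).

The default ROI-to-network partition uses contiguous blocks of sizes
DMN 22, ATT 14, SUB 12, AUD 8, VIS 14, SEN 20, mirroring the typical
granularity of AAL-90 network assignments (auditory small, DMN and
sensorimotor large).  It is a synthetic stand-in — real analyses must supply
their own mapping file — and ships as
`extdata/synthetic_rsn_partition_90.tsv`.

Because the analysis consumes only Pearson correlations, a Gaussian model
controls the target quantities exactly.  Temporal autocorrelation is *not*
simulated by default (an AR(1) knob exists, default off): autocorrelation
would reduce the effective number of samples behind each correlation
estimate without changing its target, and leaving it off keeps the
correlation targets exact.  The generator does not model scanner artifacts,
head motion, hemodynamics, negative correlation structure, or
subject-specific connectivity fingerprints.  Consequently, passing
end-to-end tests shows that the *pipeline recovers the designed covariance
structure at realistic sample sizes and noise*, not that effects in real
patient cohorts are reproduced — edge-level clinical findings depend on
access-restricted scan data and are out of scope.

# Reproducibility and problem sizes

Every stochastic sub-step (cohort draws, permutation streams per contrast
and level, random-reference ensembles) derives its own 32-bit stream from
the master seed, so a full run is deterministic — two runs of `run_demo()`
with the same seed write byte-identical tables — and results never depend on
the order in which memoized reference ensembles (keyed by node count, edge
count, ensemble size and seed) are first requested.

The validation suite exercises: the metric oracle on 200 random graphs with
N ≤ 12; small-world self-consistency at N = 90, density 0.3, 100-graph
references over 20 seeds; type-I calibration of the permutation test at
1,000 replicates (group sizes 35 vs 25); a full null-cohort run (all stages
drawn from the NC covariance, 1,000 permutations) checked for ≤ 8%
rejections per contrast; and 20-seed end-to-end pattern recovery at the full
cohort size, requiring ≥ 90% correct (network, metric) labels and the 4-vs-2
homogeneous split in ≥ 18/20 seeds.  These sizes keep the whole suite within
a typical CI budget while leaving the study conditions (cohort size, T,
effect sizes, the 45-density sweep) at their defaults.

# Known limitations

* The trajectory tolerance rule, the default partition and the
  between-network baseline are package choices where the field has no
  canonical value; all are configuration-exposed.
* Char on fragmented graphs is a pair-restricted mean; comparisons at very
  low sparsity mix connectivity and distance effects (the `connected` flag
  lets users filter).
* Covariate adjustment (age, sex), longitudinal modeling, weighted-graph
  and nodal metrics, and data-driven network discovery are out of scope.
* The "five RSN" naming in the source literature is inconsistent with its
  own list of six networks; this package implements six throughout.
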