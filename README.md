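# stagenet

Graph-theoretic analysis of how the resting-state functional connectome
changes across the ordered disease stages of Alzheimer's progression:
normal controls (NC), early and late mild cognitive impairment (EMCI,
LMCI), and AD.

The package is aimed at neuroimaging researchers who already have ROI time
series (one T × N matrix per subject, e.g. 130 volumes × 90 AAL regions)
and want a tested, reproducible pipeline from those matrices to group-level
graph statistics and trajectory patterns — plus a synthetic cohort
generator that makes the whole pipeline testable end to end without access
to restricted patient data.

## What it computes

For each subject, Pearson correlation gives a connectivity matrix, which is
binarized at a sweep of sparsities S ∈ [0.08, 0.52] (step 0.01; the range
can be re-derived from the control group via the mean-degree criterion
`k̄ ≥ 2 log N` and the small-worldness floor SW ≥ 1.1). On each binary
graph five global metrics are evaluated:

| metric | definition |
|---|---|
| Char | mean shortest-path hops over (reachable) node pairs |
| Effi | mean of 1/d<sub>ij</sub> over pairs, 1/∞ = 0 |
| Clus | mean over nodes of t<sub>i</sub> / C(k<sub>i</sub>, 2) |
| Tran | Σ 2t<sub>i</sub> / Σ k<sub>i</sub>(k<sub>i</sub> − 1) |
| SW | (C/C₀) / (L/L₀) against 100 size- and density-matched random graphs |

Each metric's curve over the sweep is summarized by its area under the
curve (AUC). The same analysis runs on six resting-state subnetworks (DMN,
ATT, SUB, AUD, VIS, SEN) by restricting the globally thresholded graph to
each network's ROIs. Groups are compared at every level (global metric
AUCs by 10,000-permutation tests; edge weights and inter-network mean FC by
Welch t-tests on Fisher-z values; subnetwork AUCs by permutation), each
family corrected with Benjamini–Hochberg FDR at 0.05, plus Pearson
correlations with MMSE scores. Finally each subnetwork's stage trajectory
of group-mean AUCs is classified as a **temperature inversion** (rise to a
peak at EMCI, then decline), a **monotonous decline**, a U-shape, or
neither, and subnetworks sharing a majority pattern are grouped into
homogeneous evolving sets.

See `vignettes/staged-connectome-analysis.Rmd` for the model details and
the design decisions (binarization modes, small-world reference matching,
metric orientation, tolerance rule).

## Worked example

```r
library(stagenet)

## synthetic four-stage cohort at the study's group sizes (35/37/33/25)
cc  <- cohort_config(seed = 42)
coh <- generate_cohort(cc)
coh
#> <stage_cohort> 130 subjects: NC=35 EMCI=37 LMCI=33 AD=25

## full study: sweep, AUCs, all six pairwise contrasts, trajectories
cfg <- study_config(n_perm_metrics = 1000, n_perm_edges = 200,
                    n_random = 50, seed = 42)
rep <- run_study(coh, config = cfg, partition = cc$partition)
rep
#> <study_report> 130 subjects, 90 ROIs, 45 densities
#>   comparisons: 24330 rows, 4199 rejections
#>   network patterns:
#>                     DMN                     ATT                     SUB
#> "TEMPERATURE_INVERSION"    "MONOTONOUS_DECLINE" "TEMPERATURE_INVERSION"
#>                     AUD                     VIS                     SEN
#> "TEMPERATURE_INVERSION" "TEMPERATURE_INVERSION"    "MONOTONOUS_DECLINE"

print(subset(rep$trajectories, metric == "clus",
             select = c(network, mean_NC, mean_EMCI, mean_LMCI, mean_AD, label)),
      digits = 4)
#>    network mean_NC mean_EMCI mean_LMCI mean_AD                 label
#> 3      DMN  0.3761    0.4287    0.4165  0.2975 TEMPERATURE_INVERSION
#> 8      ATT  0.4374    0.3976    0.3831  0.3311    MONOTONOUS_DECLINE
#> 13     SUB  0.3683    0.4280    0.4165  0.3143 TEMPERATURE_INVERSION
#> 18     AUD  0.3662    0.4281    0.4098  0.2930 TEMPERATURE_INVERSION
#> 23     VIS  0.3723    0.4281    0.4135  0.3144 TEMPERATURE_INVERSION
#> 28     SEN  0.4363    0.4039    0.3816  0.3280    MONOTONOUS_DECLINE
```

The subnetwork clustering AUCs rise from NC to a peak at EMCI and then fall
for the four inversion networks, and fall monotonically for SEN and ATT —
the two evolving patterns the generator encodes and the classifier
recovers.

The pattern labels recover the structure the generator encodes: the four
networks whose within-network coupling rises to a peak at EMCI are labeled
temperature inversions, the two with strictly decreasing coupling are
monotonous declines. `write_study_report(rep, "out/")` writes every table
as TSV (stamped with the config hash) plus `run_meta.json`; runs with the
same seed are byte-identical.

A thin command-line front end with `simulate`, `run`, `demo` and `metrics`
subcommands is installed at `inst/cli/stagenet.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/stagenet.R", package="stagenet"))')" \
    demo --out out/ --seed 42
```

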