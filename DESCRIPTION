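Package: stagenet
Title: Graph-Theoretic Analysis of Functional Connectome Change Across Disease Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary brain functional networks from region-of-interest
    (ROI) time series by Pearson correlation and sparsity thresholding, sweeps a
    range of network densities, and summarizes five global graph metrics
    (characteristic path length, global efficiency, clustering coefficient,
    transitivity, small-worldness against a matched random reference) by their
    area under the curve. Supports resting-state subnetwork (RSN) analysis,
    nonparametric permutation tests and Welch t-tests with Benjamini-Hochberg
    false-discovery-rate correction, Mini-Mental State Examination (MMSE)
    correlations, and classification of subnetwork metric trajectories across
    ordered disease stages (NC, EMCI, LMCI, AD) into "temperature inversion"
    and "monotonous decline" patterns. Includes a synthetic cohort generator
    with stage-dependent block covariance for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
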