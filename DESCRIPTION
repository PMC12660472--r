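Package: nfmed
Title: Real-Time fMRI Neurofeedback Meditation Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for intermittent real-time fMRI
    neurofeedback (NF) targeting posterior cingulate cortex (PCC) deactivation
    during focused-attention meditation. Provides a synthetic-data generator
    for block-design NF runs and behavioural cohorts, a streaming
    (incremental) GLM scoring engine with dynamic voxel selection, online
    confound residualization, thermometer feedback mapping and yoked-sham
    replay, offline block-GLM and generalized psychophysiological interaction
    (gPPI) estimation with cluster-level permutation inference, and the
    behavioural endpoint analyses (slope ANOVAs, difference-score ANCOVAs,
    exact rank-sum tests, Benjamini-Hochberg FDR, partial correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
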