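Package: adaptrace
Title: Contrast-Adaptation Analysis for Calcium-Imaging and Spike Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify contrast adaptation of visual-cortex neurons from
    two-photon calcium-imaging fluorescence traces and extracellular spike
    trains. Implements delta-F/F normalization (pre-stimulus baseline and
    rolling-percentile variants), constrained double-Gaussian direction-tuning
    fits, Z-score responsiveness classification, per-cell adaptation-slope
    estimation, optogenetic cell-type classification, behavioral trial
    classification (locomotion, saccades, licking), session trajectories with
    exponential fits, and rank-based group comparisons across behavioral states
    and stimulus-relevance conditions. Includes a synthetic-data generator with
    ground-truth adaptation parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
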