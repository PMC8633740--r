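Package: metaconn
Title: Consensus Group-ICA and Drug-Placebo Resting-State Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of placebo-controlled within-subject
    pharmacological resting-state fMRI studies. Identifies consensus
    resting-state networks by repeated group ICA with randomized scan order
    and spatial-correlation matching, estimates subject network maps and time
    courses by dual regression, tests within-network drug effects with
    threshold-free cluster enhancement (TFCE) and sign-flip permutation
    inference, tests between-network Fisher-z edge changes with
    network-based-statistic (NBS) permutation inference, and relates
    connectivity change to subjective drug response (peak change scores,
    repeated-measures ANOVA, Bonferroni-corrected correlations). Includes a
    synthetic-study generator that plants known spatial networks,
    condition-dependent between-network correlations, motion spikes and
    drug-responsive ratings, so every stage can be validated against ground
    truth. Minimal NIfTI-1 input/output is built in.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
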