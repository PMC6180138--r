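Package: empathnet
Title: Longitudinal Ising Network Analysis of Empathic-Communication
    Questionnaires
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates psychometric symptom networks from binarized
    Likert questionnaire data with nodewise l1-penalized logistic
    regression and extended-BIC model selection (the eLasso approach to
    the Ising model), and compares regional network structure between
    two measurement occasions. Ships item metadata and binarization
    rules for four self-report instruments (DASS-21, EQ-short, JSE-S,
    EES), dual-category prevalence filtering of items, weighted graph
    centralities with rank-based hub detection, two-level map-equation
    community detection, all-pairs shortest-path profiling, and a
    permutation test for pre/post change in regional measures based on
    refitted pseudo-networks. A synthetic-data module generates
    ground-truth Ising models, Gibbs-samples binary responses, expands
    them back to Likert scales, and plants known pre/post changes for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
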