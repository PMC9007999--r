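Package: consensusbn
Title: Consensus Bayesian Network Inference for Cell-Level Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers directed acyclic graphs linking oncogene expression to
    the cellular composition of a tissue from samples-by-features tables,
    such as digital-cytometry outputs. Implements a four-step consensus
    workflow: rule-based blacklists encoding prior causal knowledge, an
    ensemble of ten structure-learning algorithms with bootstrap model
    averaging, selection of a consensus seed whitelist by node-level
    BIC minimisation with cycle exclusion, and a final constrained hybrid
    search. Fitted linear-Gaussian networks support logic-sampling
    conditional-probability queries and quantile contrasts. A synthetic
    data module generates ground-truth networks with binary root
    attributes and zero-inflated features for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
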