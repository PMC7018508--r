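Package: kincycle
Title: Inheritance of Cell-Cycle Length on Lineage Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of cell-cycle-length inheritance in time-lapse lineage
    trees of proliferating cells. Provides kinship-resolved Spearman
    correlation patterns with tree-level bootstrap confidence bounds and a
    censoring-aware truncation rule; bifurcating autoregressive (BAR)
    Gaussian latent-variable models of inheritance with exact whole-tree
    likelihoods, maximum-likelihood fits and Bayesian model evidence by
    Monte-Carlo integration; a mechanistic growth-progression simulator with
    a minimum-size division checkpoint; approximate Bayesian computation for
    fitting the simulator to observed correlation patterns; and synthetic
    lineage-tree generators emulating live-cell imaging data, including cell
    loss, death and movie-end censoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
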