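Package: tpinteract
Title: Target-Pathway Interaction Inference from Drug Screens by
    Bayesian Matrix Factorization with Side Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multitask analysis of drug-response screens (log-IC50 matrices
    of drugs by cell lines) that links drug targets to signaling-pathway
    activation. A Bayesian matrix factorization model with side information
    on both axes (binary protein-target profiles for drugs, pathway activity
    scores for cell lines) is fitted by Gibbs sampling; the product of the
    two posterior link matrices yields a signed target-by-pathway interaction
    matrix whose entries are significance-tested against a permutation null
    with Benjamini-Hochberg-Yekutieli correction. Includes a
    perturbation-footprint pathway scorer (multiple linear model on
    perturbation z-scores with per-pathway gene selection), cold-start
    cross-validation harnesses for four prediction regimes, tissue-level
    report selectors, and a synthetic-screen generator with planted
    interaction structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    optparse
Config/testthat/edition: 3
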