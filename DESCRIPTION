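Package: fluencynet
Title: Individual Semantic Networks from Verbal Fluency Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates individual semantic networks from semantic (verbal)
    fluency lists under a noisy censored random walk model. Fluency data are
    modelled as a random walk on an undirected semantic network in which
    revisited items are emitted (producing a perseveration) with probability
    p_emit and hidden otherwise; the exact list likelihood is computed with
    absorbing Markov chain fundamental matrices. Networks are estimated by
    maximum a posteriori stochastic edge-toggle search with a grid search
    over p_emit and an edge-wise prior anchored to a reference association
    network. Includes a generative simulator for synthetic cohorts,
    permutation ("mock") null ensembles and delta metrics for size-corrected
    network comparison, standard network measures including a small-world
    coefficient, and group-level statistics (Welch-gated t tests, logistic
    regression with stepwise AIC selection, and stratified split-half
    cross-validation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
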