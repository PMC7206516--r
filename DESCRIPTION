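Package: npbnet
Title: Hierarchical Bayesian-Network Modelling of Neuropsychological Test Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian-network analysis of neuropsychological (NP)
    test batteries and cognitive status (healthy control, Alzheimer disease,
    non-Alzheimer dementia). Provides k-medoids (PAM) discretization of
    continuous test scores with silhouette-guided selection of the number of
    intervals, correlation-based cognitive-function clustering, BIC/MDL
    score-based structure learning by hill-climbing and tabu search with
    bootstrap model averaging, maximum-likelihood and Bayesian conditional
    probability table estimation, Markov-blanket extraction with adjusted
    degrees-of-freedom conditional-independence tests, likelihood-weighting
    and exact posterior inference of cognitive status under partial evidence,
    and stratified 10-fold cross-validated diagnostic evaluation. A synthetic
    cohort generator with a configurable planted ground-truth network makes
    the full pipeline testable without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
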