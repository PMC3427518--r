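Package: spectrabc
Title: Spectral ABC-SMC Inference for Models of Protein Interaction
    Network Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Likelihood-free Bayesian inference for stochastic models of
    protein interaction network growth.  Candidate models (duplication-
    divergence with and without complementarity, linear preferential
    attachment, generalized scale-free growth, and mixed duplication/edge-
    addition schemes) are fitted to an observed undirected network with an
    approximate Bayesian computation sequential Monte Carlo sampler whose
    data distance is the Umeyama spectral lower bound on graph edit
    distance.  A uniform node-sampling model corrects for interactome
    incompleteness, joint model/parameter particles provide marginal model
    posteriors, and posterior model averaging yields predictive network
    statistics such as the degree distribution of the unobserved full
    network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
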