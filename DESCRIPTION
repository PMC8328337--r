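Package: phlsm
Title: Penalized Homophily Latent Space Models for Directed Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian latent space modeling of directed binary networks with
    node-specific popularity scales and penalized homophily covariates. Fits
    logistic latent-distance models by Metropolis-Hastings within Gibbs with
    ridge or adaptive-LASSO regularization of pairwise attribute effects,
    simulates directed networks with power-law in-degree heterogeneity,
    supports a Gaussian-mixture latent prior for clustered networks, and
    evaluates link prediction, variable selection and parameter recovery.
    A thin command-line interface covers simulation, fitting, prediction
    and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
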