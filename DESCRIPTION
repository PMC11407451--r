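Package: netmim
Title: Network-Based Bayesian Integration of Methylation and Expression
    with Block Missingness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-layer Bayesian hierarchical model for vertical multi-omics
    integration. A mechanistic layer regresses each gene's expression on its
    promoter methylation probes with Dirac spike-and-slab priors, splitting
    expression into a methylation-regulated part and a residual part; a
    clinical layer regresses a continuous, binary, or right-censored outcome
    on clinical covariates and the two expression components, with a Markov
    random field prior over a gene-gene network coupling the selection
    indicators. Whole-sample block missingness in either omics layer and
    latent outcomes for probit and accelerated-failure-time responses are
    handled by MCMC data augmentation. Includes posterior-inclusion-
    probability summaries with Bayesian FDR thresholding, Bayesian model
    averaged prediction, a simulation-study generator, penalized two-stage
    baselines, and a cross-validation scheme for deciding whether to retain
    incomplete subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
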