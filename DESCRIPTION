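Package: netgic
Title: Personalized Gene Network Inference with a Sample-Specific
    Generalized Information Criterion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sample-specific (personalized) gene regulatory networks
    from expression data using a kernel-weighted elastic-net varying-coefficient
    model, in which edge weights vary with a continuous sample characteristic
    (a "modulator", e.g. a drug-sensitivity Z-score). Hyperparameters
    (regularization strength, L1/L2 mixing, and kernel bandwidth) are selected
    by a sample-specific Generalized Information Criterion (GIC) whose bias
    term is derived through a local quadratic approximation of the L1 penalty,
    alongside comparator criteria (AIC, AICc, BIC, HQC, EBIC, BIC-p) and k-fold
    cross-validation. Includes downstream network operations (group medians,
    cross-condition consensus, top-fraction edge filtering, drug-sensitivity
    modules, regulate-effect-change scoring) and a Monte Carlo simulation
    framework benchmarking edge selection and weight estimation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
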