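Package: vbnetrec
Title: Sparse Undirected Network Reconstruction with Variational Bayes
    Spike-and-Slab Regression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs sparse undirected networks among gene expression
    traits, genotypes and downstream phenotypes by neighborhood selection
    with spike-and-slab variational Bayes regression.  Each node is
    regressed on all other nodes under a spike-and-slab prior whose
    inclusion fraction is truncated so that the expected model size grows
    like the square root of the sample size; multi-restart Bayesian model
    averaging weights posterior inclusion probabilities by the evidence
    lower bound, and edge scores are averaged across the two directions of
    regression before thresholding.  Includes lasso baselines with bounded
    type-I error (Meinshausen-Buhlmann penalty choice, randomized lasso
    with stability selection, cross-validated lasso and adaptive lasso),
    a random-graph simulator with moralized precision matrices, precision-
    recall benchmarking utilities, principal-component confounder
    correction, delimited-text readers/writers and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
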