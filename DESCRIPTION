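Package: plnet
Title: Permutation-Stabilised Lasso Inference of Gene Association Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers undirected gene association networks from expression
    profiles by intercept-free lasso neighbourhood selection. Each gene is
    regressed on all remaining genes with a shrinkage factor estimated once
    by cross-validation on a gene subset; the selected neighbours are then
    stabilised by a response-permutation counter procedure with an
    empirical-null significance gate, assembled into a binary adjacency
    matrix and symmetrised. Includes a linear structural-equation simulator
    of scale-free gold-standard benchmarks, and network evaluation against
    a gold standard via confusion counts, the Matthews correlation
    coefficient, and degree and betweenness-centrality correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    parallel,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
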