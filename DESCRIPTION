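Package: psychonet
Title: Psychometric Ising Network Analysis for Binary Survey Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation and structural analysis of psychometric networks over
    binary survey indicators. Implements eLasso network estimation (nodewise
    L1-penalized logistic regression with extended-BIC model selection,
    and/or-rule symmetrization, unpenalized covariate adjustment, survey-weighted
    likelihoods, and skip-logic edge exclusion), categorical assortativity,
    strength and betweenness centrality, signed spin-glass community detection
    by simulated annealing, configuration-model null networks, node-ablation
    tests, survey-weighted bootstrap inference with Bonferroni adjustment, and
    a penalty-parameter sensitivity sweep. A planted-structure Ising simulator
    (Gibbs sampler with covariate-shifted thresholds, deterministic skip logic,
    and survey weights) makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
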