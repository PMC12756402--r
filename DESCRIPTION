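Package: bdgphylo
Title: Birth-Death-Gain Analysis of Gene and Domain Family Counts on Species Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Likelihood-based analysis of phylogenetic profiles of gene or
    protein-domain family copy numbers. Models family-size evolution as a
    linear birth-death process with gain (immigration) on a rooted species
    tree, with branch-specific rates modulated by family-specific
    discretized-gamma rate factors and a Poisson root prior. Provides staged
    maximum-likelihood fitting, posterior ancestral states and per-branch
    family-event probabilities, Dollo parsimony reconstruction for
    comparison, classification of lineages into evolutionary modes,
    high-confidence parallel-event censuses, permutation tests for
    rate-function association, significance-tested hierarchical clustering
    of family rate profiles, and an exact stochastic simulator of the
    process for validation and power studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    MASS,
    cluster,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    knitr
Config/testthat/edition: 3
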