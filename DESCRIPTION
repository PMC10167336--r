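Package: morphoclade
Title: Phylogenetic Comparative Analysis of 3-D Landmark Shape Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for phylogenetic comparative geometric morphometrics:
    generalized Procrustes alignment with bending-energy sliding
    semilandmarks, principal component and phylogenetically aligned
    component ordination, multivariate phylogenetic signal (Kmult),
    penalized-likelihood multivariate phylogenetic linear models with
    permutation MANOVA/MANCOVA, Mk-model fitting and stochastic character
    mapping, regime-specific Brownian-motion rate estimation, morphological
    disparity (Procrustes variance) with bootstrap tests,
    disparity-through-time curves with Brownian envelopes, and
    reversible-jump MCMC inference of branch-specific evolutionary rate
    shifts. Includes a synthetic-data generator emulating a multi-specimen,
    multi-species 3-D landmark study on a phylogeny so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    picante
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
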