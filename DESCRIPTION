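Package: phylotopo
Title: Testing Geographic and Morphological Hypotheses Against Molecular Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether geography or morphology predicts a
    molecular phylogeny. Builds alternative topological hypotheses (a
    neighbor-joining tree on great-circle distances between species or
    ecoregion centroids, a tree from discrete morphological characters under
    Mk/Mkv models, or a prior classification expressed as monophyly
    constraints), scores each hypothesis against molecular sequence data by
    constrained Bayesian MCMC with stepping-stone marginal-likelihood
    estimation and Bayes factors, and quantifies morphological homoplasy by
    stochastic character mapping (consistency and homoplasy indices, state
    dwell times, and anatomical-region aggregation). Includes a synthetic-data
    generator (trees, partitioned sequences, convergent morphology, spatially
    autocorrelated localities) so the whole pipeline can be exercised and
    calibrated without external data, plus range-area and short-range-endemism
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    sp,
    stats,
    tibble,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
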