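Package: ptnet
Title: Plant Trait Networks from Species-by-Trait Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds plant trait networks (PTNs) from species-by-trait tables:
    pairwise Pearson correlations thresholded at a significance level into a
    binary adjacency matrix, with the three network parameters used in trait
    ecology (degree, edge density, Newman-Girvan modularity with community
    detection), hub-trait identification and trait-category importance.
    Uncertainty is quantified by a species bootstrap, species-richness
    dependence by a rarefaction simulation, and groups (life-form, aridity
    region) are compared with Duncan's multiple range test and Welch t-tests.
    Includes a synthetic-data generator with planted block correlation
    structure so every stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
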