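Package: modulrate
Title: Craniofacial Modularity, Integration, Evolutionary Rates and
    Evolvability from 2-D Landmark Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparative analyses of
    morphological modules from two-dimensional landmark data and a
    time-calibrated phylogeny. Reads TPS landmark files and Newick/NEXUS
    trees, performs generalized Procrustes superimposition with
    tangent-space projection, and provides phylogenetic (Brownian-motion)
    versions of the covariance-ratio modularity test, two-block
    partial-least-squares integration, per-module multivariate
    evolutionary-rate comparison against simulated equal-rate nulls, and
    random-skewers evolvability indices (evolvability, respondability,
    conditional evolvability, autonomy, constraints) from phylogenetically
    corrected P-matrices. Includes a synthetic-study generator that
    simulates modular multivariate Brownian motion on birth-death trees so
    every stage of the pipeline can be exercised without specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
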