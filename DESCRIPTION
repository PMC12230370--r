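Package: macrosem
Title: Spatial Piecewise Structural Equation Models for Species Richness
    Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Assembles gridded species-richness data from phylogenies and
    species ranges and asks what drives the richness gradient. Computes
    tip-level speciation-rate (DR, inverse equal splits) and
    evolutionary-time (tip age) metrics averaged over stochastically
    imputed time-calibrated trees, screens spatially autocorrelated
    predictors with Dutilleul's modified t-test, fits every structural
    equation as a simultaneous-autoregressive (SAR) error model by profile
    maximum likelihood, and ranks candidate piecewise structural equation
    models by AICc with d-separation tests and standardized direct,
    indirect, and total effects. A synthetic-data module generates
    birth-death trees, autocorrelated environmental fields, spreading-dye
    ranges, and cell tables with known coefficients so every stage has a
    parameter-recovery surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    phytools,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
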