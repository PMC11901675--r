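Package: mgkinetics
Title: Ion-Depletion Uptake Kinetics for Plant Nutrient Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of ion-depletion (solution-depletion) uptake-kinetics
    experiments in hydroponically grown plants. Fits quadratic depletion
    models to solution concentration-versus-time series, derives the
    kinetic parameters Imax (maximum uptake rate, scaled by solution
    volume and fresh root weight) and Cmin (solution concentration at
    zero net uptake), and computes treatment-versus-control differences.
    Includes the supporting assay arithmetic (dilution back-calculation,
    root mineral content from acid digests, relative gene expression by
    the 2^-ddCt method), an inferential layer (one-way ANOVA with
    Duncan's multiple range test and compact letter displays, PCA,
    redundancy analysis, and a chain-structured partial-least-squares
    path model with bootstrap significance), and a synthetic-data
    generator that emulates the two-cultivar, seven-treatment magnesium
    depletion design so the whole pipeline is testable without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
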