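Package: podomech
Title: Mechanobiological Analysis of Podocyte Sarcomere-Like Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for studying contractile sarcomere-like
    structures (SLSs) in cultured kidney podocytes. Provides seeded synthetic
    generators for striated two-channel fluorescence images, microbead clouds
    under known deformations, and cell phenotype populations; intensity-profile
    extraction and sub-pixel peak detection for sarcomeric spacing statistics;
    Green-Lagrange strain mapping from matched bead displacements via windowed
    weighted affine fits; a quadratic-tetrahedron finite-element model of an
    eigenstrain-contracting cell process bonded to an elastic substrate, with
    substrate-stiffness and contractility sweeps; and phenotype scoring,
    detachment-assay summaries, and thin ANOVA/Tukey/Sidak wrappers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    EBImage,
    tiff,
    emmeans,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
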