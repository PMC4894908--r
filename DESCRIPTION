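Package: mucilager
Title: Quantitative Phenotyping of Arabidopsis Seed Mucilage
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reproducible pipeline for quantifying Arabidopsis seed
    mucilage phenotypes from light-microscopy images and chromatography
    tables. Implements color-threshold segmentation with connected-component
    particle analysis and circularity filtering for ruthenium-red stained
    mucilage capsules, perpendicular intensity profiling with trapezoidal
    integration for Pontamine Fast Scarlet 4B (S4B) cellulose staining,
    birefringent-area-per-seed scoring under polarized light,
    internal-standard normalization of HPAEC-PAD monosaccharide data,
    efficiency-corrected qRT-PCR relative expression (Pfaffl method with a
    two-gene geometric-mean normalizer), reference-relative phenotype
    classification into five mucilage classes, and a synthetic-data
    generator with known ground truth for every assay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
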