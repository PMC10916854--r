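Package: cargoscreen
Title: Analysis of Arrayed CRISPR High-Content Screens of Dynein Cargo Localization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of arrayed CRISPR loss-of-function screens that
    read out dynein-driven cargo localization by high-content imaging. Provides a
    synthetic-screen generator with planted ground truth (384-well plate layouts,
    per-cell feature tables, rendered multi-channel well images), per-cell image
    quantification (nucleus and cytoplasm segmentation, multi-scale spot detection,
    ring-based perinuclear localization ratios, micronucleus and MTOC counting,
    texture and morphology features), plate-level robust normalization (rZ,
    two-point) and robust Z-prime assay windows, linear-discriminant composite
    endpoints, SD-threshold hit calling with confound exclusion, and
    phenotypic-fingerprint reduction and clustering for co-functional gene
    discovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    ape,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
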