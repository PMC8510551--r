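Package: phenoscreen
Title: Phenotypic Analysis of Arrayed Bacterial CRISPRi Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of arrayed CRISPRi essential-gene
    libraries in bacteria: pooled relative fitness from sgRNA spacer
    counts, cross-contamination quality control, plate-reader growth-curve
    features (maximum growth rate and lag time) with wild-type
    normalization, single-cell contour morphometrics (midline meshing,
    length, width, volume, instantaneous growth rate), strain-level
    aggregation with robust (MAD-based) statistics and plate-effect
    correction, outlier classification, and hypergeometric category
    enrichment. Includes a synthetic-data generator emulating the
    statistical structure of every input so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
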