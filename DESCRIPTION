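Package: ssir
Title: Superposing Significant Interaction Rules for Untargeted GC-MS
    Classification
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Untargeted chemometric classification of GC-MS volatile
    profiles. Raw chromatographic scans are discretized onto a rectangular
    retention-time by ion-mass grid, normalized and binarized, and
    class-discriminating grid nodes are selected by scoring conjunction
    rules of node levels against an exact hypergeometric enrichment null
    (the superposing significant interaction rules, SSIR, selector).
    Selected variables feed a principal component analysis and a Fisher
    linear discriminant, validated by full-pipeline leave-one-out
    cross-validation. Includes readers for mzML and long-format scan
    tables, extracted-ion chromatogram utilities, and a synthetic
    two-class chromatogram generator with a ground-truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mzR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
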