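Package: msiScreen
Title: Rule-Out Pre-Screening of Microsatellite Instability from
    Whole-Slide Tile Features
Version: 0.3.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Slide-level rule-out screening of microsatellite instability
    (MSI) in colorectal cancer from haematoxylin-eosin whole-slide images
    represented as bags of tile features. Implements micron-accurate tiling
    with foreground filtering, an automated two-stage quality check (blur
    flagging and tumour-content gating), a Chowder-variant multiple-instance
    learning classifier with extreme (top/bottom) score pooling, a
    sensitivity-guaranteed calibration step that derives the operating
    threshold from a small set of known-MSI slides, screening metrics with
    bootstrap confidence intervals, and the reliability statistics used to
    assess inter-scanner, intra-scanner and inter-block reproducibility
    (Cohen's and Fleiss' kappa, Pearson correlation, exact McNemar,
    inter-block RMSE). A seeded synthetic-cohort generator provides tile
    images and feature bags with the statistical structure the pipeline
    assumes, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
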