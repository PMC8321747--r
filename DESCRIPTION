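Package: chemfuse
Title: Multi-Block Data Fusion for Chromatographic and Spectroscopic Fingerprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for geographical-origin classification of natural products
    from instrumental fingerprints. Implements a complete chemometric pipeline:
    correlation-optimized warping (COW) of chromatograms, Savitzky-Golay
    second-derivative preprocessing, spectral band deletion, Kennard-Stone
    calibration/validation partitioning, PLS-DA with VIP scores, random forest
    with OOB-based parameter screening, Boruta all-relevant feature selection,
    PCA feature extraction, and low-, mid- and high-level data fusion with
    fuzzy aggregation connectives. Includes a seeded synthetic fingerprint
    generator with known class structure for end-to-end validation, and the
    evaluation statistics (per-class efficiency, total accuracy, permutation
    testing of PLS-DA models) used to compare fusion strategies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
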