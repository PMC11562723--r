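Package: pmwave
Title: Wavelet-Based Hourly PM2.5 Exposure Surfaces from Gap-Filled Satellite AOD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds hourly, gap-free fine-scale PM2.5 exposure surfaces from
    gridded predictors. Satellite aerosol optical depth (AOD) fields with
    cloud-induced gaps are filled per hour by a random-forest model driven by
    background-model AOD and meteorology; gridded predictors are decomposed
    into additive multiresolution components with orthogonal Daubechies
    wavelets; high-concentration training rows are augmented by synthetic
    minority oversampling (SMOTE); and a pooled random-forest model is
    evaluated by out-of-bag metrics, random 10-fold cross-validation, and
    leave-monitors-out spatial cross-validation. Includes a synthetic-scene
    generator with known statistical structure so the full pipeline is
    testable end to end, plus grid alignment utilities (nearest-cell
    assignment, bilinear regridding, inverse-distance-weighted downscaling,
    observation merging) and a plain-text gridded field format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    ranger,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
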