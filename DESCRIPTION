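Package: mprabc
Title: Barcode-Level Linear Modelling of Massively Parallel Reporter Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis of massively parallel reporter assay (MPRA)
    count data at the level of individual barcodes. Provides preprocessing of
    barcode count tables (minimum-count and minimum-barcode filters, 3-SD RNA
    outlier removal, percentile-capped barcode downsampling), construction of
    barcode-as-sample count frames for variant (ref/alt) and element designs,
    log2 RNA/DNA ratio computation with replicate-level library normalization,
    mean-variance trend precision weights, generalized least squares with a
    consensus within-replicate correlation, empirical Bayes moderation of
    residual variances, moderated t-tests with Benjamini-Hochberg adjustment,
    and a threshold t-test of element activity against negative-control
    percentiles. Includes a negative-binomial simulator of barcode-level MPRA
    data with configurable effect groups and a multiplicative RNA outlier
    injector for validation and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    statmod,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
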