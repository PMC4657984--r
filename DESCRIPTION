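Package: crownpheno
Title: Tree Species Discrimination from Multitemporal Crown Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Object-based discrimination of deciduous tree species from a
    time series of very-high-resolution orthomosaics. Extracts shadow-filtered
    spectral statistics, band ratios, normalized indices, vegetation indices
    and gray-level co-occurrence texture metrics per delineated tree crown,
    scores species separability with balanced repeated random-forest
    classification averaged over out-of-bag errors, and exhaustively ranks
    single-, two- and three-date survey combinations to locate the optimal
    acquisition window. Ships a synthetic phenology-scene generator so the
    whole pipeline is testable without aerial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    randomForest,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
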