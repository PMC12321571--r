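Package: arcquant
Title: Quantitative Image Analysis of Perinatal Subventricular Migratory Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the image-derived measurements used in comparative
    studies of the neonatal subventricular zone and its "Arc" of migratory
    young neurons: per-cell multiplexed smFISH transcript quantification
    (Renyi-entropy thresholding, pixel-percentage expression, median
    background zeroing, clustering and marker-based subtype assignment),
    permutation-based cell-type neighborhood interaction analysis with
    cross-image aggregation, topographic mapping of cells along migratory
    stream paths, and section-level morphometrics (area ratios,
    gyrification index, tier profiles, and conical-frustum serial-section
    volume estimation). A synthetic-data module generates probe images,
    cell maps, section series and folded contours with planted ground
    truth so that every stage of the pipeline can be validated without
    access to raw specimen images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    tiff,
    EBImage
Suggests:
    mclust,
    uwot,
    withr,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
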