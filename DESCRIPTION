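Package: fluorid
Title: Genotype Identification of Tracked Flies from Fluorescence Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for group behavioral experiments in which
    one subpopulation of animals carries a fluorescent transgene (e.g. thoracic
    eGFP in Drosophila). Given per-fly tracking data (position, orientation,
    body-ellipse axes) and synchronized fluorescence images, the package builds
    oriented per-fly regions of interest, computes dimensionless fluorescence
    metrics (Max 5% Ratio and Skewness), calibrates a combined-metric classifier
    on homogeneous groups by a weight-by-threshold grid sweep, and assigns
    genetic identity (GFP / non-GFP) to each fly in heterogeneous groups, with
    or without prior knowledge of the expected number of labeled animals. A
    synthetic scene generator produces paired infrared and fluorescence image
    stacks with ground truth so the whole pipeline is testable without
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
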