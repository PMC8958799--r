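Package: rootlapse
Title: Time-Lapse Root Phenotyping from Plate Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for seed germination and root growth
    assays on agar plates imaged as hourly time-lapse series. Segments seed and
    root pixels (classical thresholding or a trainable pixel classifier with a
    patch/stitch contract), tracks per-seed instances through expanding bounding
    boxes with neighbor-overlap truncation, converts root pixels to calibrated
    skeleton lengths, detects germination and fits per-seed growth rates, and
    compares genotypes by germination index and growth rate with one-way ANOVA,
    Tukey HSD and compact letter displays. Includes a fully ground-truthed
    synthetic plate generator, optics bench arithmetic (USAF-1951 resolving
    power, line-probe modulation contrast, field-of-view), and a simplified
    depth-from-focus profilometry with triangulated surface export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    multcomp,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
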