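Package: ihcquant
Title: Quantitative Scoring of Brightfield Immunohistochemistry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies chromogenic (DAB/hematoxylin) immunohistochemistry
    from 8-bit RGB brightfield micrographs. Implements Beer-Lambert color
    deconvolution into per-stain optical-density maps, a knockout-controlled
    signal-to-noise specificity index for antibody validation, wide-line
    zonation profiling with LOWESS smoothing, object-level DAB scoring
    (nuclei morphometrics, cytosolic and endothelial signal, percent
    area above threshold), difference-of-Gaussian puncta detection with a
    per-cell amplitude filter, and matrix-level expression scores
    (percent-expressing tables, zone-score aggregation of log-fold-change
    matrices). A synthetic-scene generator renders two-stain brightfield
    images with exact ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
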