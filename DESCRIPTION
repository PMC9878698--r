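Package: chillscan
Title: Tray-Image Rosette Phenotyping and Chilling-Tolerance Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: High-throughput digital phenotyping of Arabidopsis rosettes grown
    in 12x12 plug trays, and the downstream genetics of chilling tolerance.
    Implements the six-step tray-image workflow (tray cropping, Hough-transform
    grid-line detection, perspective rectification, per-cell segmentation and
    colour-filter rosette-area measurement), growth-rate and broad-sense
    heritability statistics, minor-allele-frequency-filtered single-SNP
    association scans by linear regression and a kinship-corrected mixed model
    with genomic-control diagnostics, promoter-aware candidate-gene calling,
    and knockout-mutant validation and expression-phenotype concordance
    classification. A synthetic-data module renders tray images with exact
    per-cell ground truth and simulates phenotype panels and genotype matrices
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    png,
    EBImage,
    vcfR,
    rtracklayer,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
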