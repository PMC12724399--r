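Package: mavescorer
Title: Scoring, Integration and Clinical Calibration of Multiplexed
    Assays of Variant Effect
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of multiplexed assays of variant effect
    (MAVEs) for ion-channel saturation mutagenesis screens: barcode
    subassembly (trough thresholding, Hamming-distance collapse, consensus
    calling), sort-seq surface-abundance scoring (weighted bin averages)
    and growth-based channel-function scoring (log-ratio enrichment over a
    drug-selection timecourse), anchor-based normalization and functional
    categorization, dominant-negative variant calling from four assay
    contexts, PCA/k-means mechanism clustering, and ACMG/ClinGen functional
    evidence calibration via binary OddsPath and continuous kernel-density
    log-likelihood ratios. A synthetic-data generator simulates barcoded
    libraries, FACS bin counts and selection timecourses from latent
    variant effects so the full pipeline is testable without sequencing
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml,
    Biostrings,
    S4Vectors,
    randomForest,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
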