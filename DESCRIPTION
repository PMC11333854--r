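Package: spotcheck
Title: One-Stop Quality Control for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quality control for multi-slice spatial transcriptomics
    experiments. Scores every cell or spot on five QC metrics (genes
    detected, total counts, mitochondrial fraction, marker-gene detection
    and a simulated-doublet kNN score), filters data sequentially at the
    slice, cell and gene level, recommends filtering thresholds via
    retention sweeps, and renders a self-contained interactive HTML QC
    report alongside the cleaned dataset. Reads and writes h5ad, reads
    MatrixMarket triplets with coordinate tables and Stereo-seq GEM text,
    and ships a seeded synthetic-data generator with planted QC defects
    for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    rhdf5,
    FNN,
    irlba
Suggests: testthat (>= 3.0.0), xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
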