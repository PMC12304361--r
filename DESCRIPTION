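Package: occupeak
Title: Differential Transcription-Factor Occupancy from Single-Nucleus
    Tagmentation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-nucleus targeted-tagmentation (CUT&Tag-style)
    experiments contrasting transcription-factor occupancy between two cell
    states. Builds binned per-cell count matrices over peak windows, applies
    read-depth and quantile quality filters, and tests each peak with a
    z-score on the log2 bin-averaged, cell-summed signal whose variance
    accounts for bin-bin covariance across cells. Includes promoter-window
    integration of bulk occupancy with differential-expression gene sets
    (zero-excluded ratios, paired t-tests, GSEA pre-ranking), Jaccard-based
    cluster-stability assessment, PCA/UMAP embedding of filtered cells, and a
    synthetic two-state fragment generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    uwot
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
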