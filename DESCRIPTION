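Package: tescape
Title: Cell-Type-Resolved Transposable Element Dysregulation Analysis for
    Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify and interpret locus-level transposable element
    (TE) dysregulation in case/control single-nucleus RNA-seq studies of the
    brain. Implements pseudobulk negative-binomial likelihood-ratio
    differential expression per cell type, a balanced-downsampling robustness
    screen for imbalanced designs, TE class/family/subfamily and evolutionary
    age annotation with enrichment tests against genomic baseline composition,
    multi-window TE-gene proximity analysis with a normalized window-selection
    matrix, and integration with chromatin accessibility (ATAC) peaks to score
    candidate TE-gene regulatory pairs. A fully seeded synthetic-data module
    generates complete desk-scale inputs (counts, metadata, interval tracks,
    peak matrices, gene lists) with planted cell-type-specific effects so the
    whole pipeline can be exercised and calibrated without any external data.
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
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    MASS,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
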