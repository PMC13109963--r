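Package: strx
Title: Spatial Transcriptomics Analysis and In Silico Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable analysis pipeline for spatial transcriptomics
    samples: per-technology quality control and normalization,
    post-processing of cell-type deconvolution results into pseudo-cells,
    spatially variable gene testing with Moran's I and permutation nulls,
    one-vs-rest cell-type marker detection by Wilcoxon rank-sum tests,
    neighborhood- and distance-based cell-cell interaction scoring, and a
    connectivity-style drug repurposing engine (rank-based enrichment
    score, permutation p-values, drug perturbation networks overlaid on
    protein-protein interaction modules, and compound selection). Seeded
    synthetic-data generators produce every input class with known ground
    truth so the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
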