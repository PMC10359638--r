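Package: chromshift
Title: Chromatin Contact and Cohesin Occupancy Shifts After Factor Depletion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics and multi-step procedures for linking transcription
    factor depletion to cohesin occupancy and 3D chromatin interaction
    changes. Implements sparse contact-matrix iterative balancing,
    distance-expected profiles and observed/expected transforms, compartment
    eigenvectors and saddle enrichment scores, aggregate peak analysis and
    rescaled domain pileups, diamond insulation scores, multi-resolution loop
    merging, responsive-loop classification, permutation nulls for loop-length
    GSEA, anchor-element enrichment and gene-category enrichment, ChIP-seq
    track quantification and normalization scalings, ChIP-MS candidate
    filtering, 4C near-cis quantification, and a synthetic-data generator
    with planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
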