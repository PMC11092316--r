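Package: cnaband
Title: Cytoband-Level Copy Number Alteration Calling from Low-Coverage
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for copy-number profiling of tumour
    samples from low-coverage whole-genome sequencing bin counts: count
    normalization and CBS-style permutation segmentation into relative
    copy-number profiles, a fit-matrix purity search (ploidy fixed at 2)
    converting relative segment levels into absolute integer copy numbers,
    cytoband- and arm-level alteration calling under a strict
    majority-of-bases rule, genomic-burden metrics, and cohort-level
    Fisher-exact enrichment, concordance and event-free-survival
    statistics. Includes a synthetic-data module that simulates
    overdispersed bin counts with known purity and copy-number ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    survival,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
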