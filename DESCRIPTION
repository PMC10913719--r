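Package: mtxbench
Title: Benchmarking Workbench for Low-Biomass Metatranscriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and evaluation workbench for taxonomic and functional
    profiling of metatranscriptomes from samples where host RNA vastly
    outnumbers microbial RNA (e.g. mucosal tissue). Generates seeded synthetic
    host-microbiome communities with full ground truth, reimplements the
    computational cores of a low-biomass profiling workflow (sliding-window
    quality trimming, k-mer based host/rRNA/virus depletion, a k-mer LCA
    classifier with confidence thresholding, Bayesian-style species-level
    count reestimation, a clade-specific marker profiler, frequency-based
    contaminant scoring, and a tiered nucleotide/translated functional
    profiler with RPK/CPM quantification), and scores the results with
    presence/absence precision, recall and F1 against the known community.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    withr,
    readr,
    stringr,
    generics,
    ggplot2,
    stats,
    utils,
    Biostrings,
    IRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
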