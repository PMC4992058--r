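Package: rechipr
Title: Enrichment Calling and Co-Occupancy Classification for ChIP-seq and
    reChIP-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a two-component binomial mixture model to paired
    treatment/control read counts from ChIP-seq or sequential ChIP
    (reChIP-seq) experiments, calls enriched regions against the fitted
    background at a chosen false discovery rate, and emits regularized,
    normalized log-enrichment scores. Includes fragment-midpoint counting
    of paired-end alignments over user-supplied regions or transcription
    start site windows, classification of regions into eight histone-mark
    co-occupancy (bivalency) classes from multiple enrichment call sets,
    gene-level class assignment, expression variability and set-enrichment
    statistics, dinucleotide sequence statistics (CpG and CpA/TpG
    observed/expected odds), and seeded simulators for counts, alignments,
    and sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    methods,
    stats,
    utils,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
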