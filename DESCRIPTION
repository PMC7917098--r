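Package: alienscan
Title: Tracing Alien Donor Chromosomes in Interspecific Introgression Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects whole alien chromosomes introgressed from a wild donor
    species into a crop recipient, as in cucumber alien addition line breeding.
    Provides a self-contained anchor-based pairwise whole-genome aligner
    (k-mer seeding, co-linear chaining, banded affine extension, one-to-one
    filtering), derivation of donor chromosome-specific sequences from the
    unaligned complement with a cross-chromosome uniqueness screen, evenly
    spaced marker selection, best-hit classification of low-depth resequencing
    reads under alignment-length and identity thresholds, sliding-window read
    profiling, and per-chromosome presence calls. A synthetic genome-evolution
    module (substitutions, indels, chromosome fusions, donor-specific
    insertions, paired-end read simulation) supplies ground-truthed inputs so
    the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
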