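Package: tyrfish
Title: Genome-Wide Specific FISH Probe Design and Cytogenetic Map Integration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing genome-wide specific probes for tyramide
    signal amplification fluorescence in situ hybridization (Tyr-FISH) of
    transcript-based markers, and for integrating the resulting cytogenetic
    positions with genetic and pseudochromosome maps. Covers repeat-aware
    extraction of primer-delimited probe candidates, an internal
    seed-and-extend off-target screen with a "dangerous hit" classification
    and least-hit probe selection, aggregation of per-metaphase hybridization
    signal measurements into relative arm positions (RPHC) and fractional
    lengths (FL), and marker-order concordance metrics (rank mismatch and
    minimal removal via longest increasing subsequence) with orientation
    detection for linkage groups. Includes seeded generators for synthetic
    genomes, genetic maps with recombination suppression, and noisy signal
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    seqinr,
    stringr,
    tibble,
    tidyr,
    withr
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
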