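Package: xenotrace
Title: Subtractive Metagenomics for Detecting and Tracing Mobile Genetic
    Elements Between Parallel Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects candidate mobile genetic elements (MGEs) disseminating
    between parallel evolving microbial communities from shotgun metagenomic
    time series. Reads from a derived sample are subtracted against the
    community's own ancestral assembly, the unmapped remainder is assembled
    into unique contigs, and contigs are attributed to allopatric donor
    communities by high-identity local alignment (xenotypic contigs), whose
    depth and breadth are then traced across all samples. Includes a
    de Bruijn unitig assembler, a seed-and-extend read mapper, a BLAST-like
    HSP finder, a mock-community benchmark simulator with ground-truth
    scoring, and Crawford-Howell enrichment statistics for MGE annotation
    categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    igraph,
    methods,
    parallel,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
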