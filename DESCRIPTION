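Package: pssmap
Title: Probabilistic Short-Read Mapping with Position-Specific Scoring Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps short sequencing reads to a reference genome by converting
    each read and its Phred quality scores into a position-specific scoring
    matrix (PSSM) under user-specified models of sequencing error, evolution
    and data-specific base modification (ancient-DNA deamination damage,
    PAR-CLIP T-to-C conversion, biased base composition), then searching an
    FM-index of the genome and its reverse complement with a best-first,
    lookahead-threshold algorithm. Reported hits carry posterior mapping
    probabilities and Phred-scaled mapping qualities, and are written as SAM.
    Includes a seeded read simulator with position-dependent quality profiles
    and an evaluation harness computing sensitivity and positive predictive
    value with MapQ filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    Rsamtools
Config/testthat/edition: 3
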