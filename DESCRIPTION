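Package: covvalley
Title: Diagnostics for Coverage Non-Uniformity in RNA-Seq Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies and dissects the peak-and-valley non-uniformity of
    fragment coverage along transcripts in stranded paired-end RNA-Seq.
    Builds per-base fragment coverage for single-isoform genes, detects
    coverage valleys on Gaussian-smoothed tracks and summarises them with a
    global valley score, corrects 3' bias against a reference sample by an
    exponential positional fit, tests fragment-end sequence preference with
    empirical position weight matrices and a column-permutation test,
    analyses UMI-based PCR duplicate rates by position and by GC bin, and
    assesses peak-versus-valley mappability with an exact contingency test.
    A fully ground-truthed synthetic fragment-library generator emulates the
    library-preparation biases under study (positional fragmentation
    propensity, fragment-end preference, GC-dependent PCR amplification,
    3' degradation) so every diagnostic can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
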