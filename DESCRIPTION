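Package: forumdomains
Title: Genome-Wide Mapping of Blunt-End DNA Double-Strand Breaks and
    Forum-Domain Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide maps of blunt-ended DNA
    double-strand breaks (DSBs) obtained by terminus-capture sequencing.
    Collapses mapped reads into forum-domain termini (FT), segments
    chromosomes into the protected forum domains lying between consecutive
    DSB hot spots, computes FT density tracks and read-subsampling
    saturation curves, tests candidate regions for FT enrichment with a
    Monte-Carlo null backed by an analytic binomial tail, and tests
    within-domain coordination of gene expression with a circular-shift
    permutation null.  Includes a synthetic-data generator that emulates
    the sequencing construct (blunt cut to nearest Sau3A/GATC site, with
    adaptor decoration) and domain-coordinated expression, so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
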