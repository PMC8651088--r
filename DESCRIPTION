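Package: tuarch
Title: Transcription-Unit Architecture Analysis for Bacterial Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Assembles bacterial transcription units from transcription start
    sites and Term-seq transcript 3'-end positions (TEPs), classifies TEPs
    into primary/secondary/intragenic/antisense/upstream categories, and
    quantifies ribosome and transcript occupancy along the resulting
    architecture. Implements the UTR enrichment degree (UED) statistic,
    metagene ribosome-occupancy profiles with an extremity/torso partition of
    coding sequences, median-of-ratios count normalization, differential
    expression and translation-efficiency calls, intrinsic-terminator
    sequence characterization against random intergenic backgrounds, and a
    seeded synthetic-data generator that emulates strand-specific RNA-seq,
    Ribo-seq and Term-seq coverage tracks for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors,
    BiocGenerics,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
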