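Package: evlongread
Title: Transcript Integrity and Degradation Analysis for Long-Read
    Extracellular Vesicle Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of nanopore long-read cDNA profiles of extracellular
    vesicle (EV) subtypes (exosomes and microvesicles). Computes per-read
    transcript coverage rates, classifies reads as intact or fragmented,
    infers the direction of RNA degradation (3' to 5', 5' to 3', or
    endonucleolytic) from terminal coverage in transcript coordinates,
    assigns multi-mapping reads to transcripts by expectation-maximization,
    and summarises transcript and biotype composition, intrinsic genes, and
    between-subtype heterogeneity statistics. Includes a fully seeded
    synthetic-data generator that emits transcript catalogs and degraded
    read populations with per-read ground truth, so every pipeline stage is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
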