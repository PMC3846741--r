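Package: bamdigest
Title: One-Command Quality-Control Digest of Aligned BAM Files
Version: 0.1.0
Authors@R: person("bamdigest", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes a comprehensive quality-control digest of a
    coordinate-sorted, indexed BAM file: sequencing-depth pileup and
    coverage thresholds, base-quality profiles, mapping and FLAG
    statistics, CIGAR base accounting, duplication and insert-size
    distributions, and base composition against a reference-genome
    metadata store. Per-base statistics are estimated from a seeded
    random subsample of reads, with a resampling module that verifies
    the subsample reproduces global statistics. Results are collected
    in a single structured bundle, screened by rule-based alerts, and
    rendered as a sectioned HTML report. A synthetic-BAM generator
    with exact ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    jsonlite,
    Rsamtools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
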