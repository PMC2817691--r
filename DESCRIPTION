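Package: rrlsnp
Title: SNP Discovery from Reduced Representation Libraries and
    RIL-Based Scaffold Anchoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, simulation-testable pipeline for single
    nucleotide polymorphism (SNP) discovery from reduced representation
    libraries (RRLs): in-silico multi-enzyme restriction digestion with
    fragment size selection, short-read simulation with per-base quality
    scores, 33-mer occurrence screening of repetitive and organellar
    reads, seeded ungapped alignment of 33 bp tags, pileup-based
    consensus SNP calling with configurable filter cascades (including
    flank-repetitiveness tests), forward simulation of recombinant
    inbred line (RIL) populations by single-seed descent, two-point
    linkage with the Kosambi mapping function, and genetic-map-based
    anchoring and orientation of assembly scaffolds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
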