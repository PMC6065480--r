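Package: fuseviz
Title: Fusion Gene Visualization via SuperTranscript References
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds intron-free superTranscript references for fusion genes
    reported by RNA-seq fusion callers, lifts transcript, protein-domain and
    gene-boundary annotation into superTranscript coordinates, quantifies
    fusion-supporting split reads from spliced alignments with anchor-length
    and read-support filters, normalizes coverage to reads per million, and
    renders IGV-compatible tracks plus multi-track sashimi-style figures.
    Includes a deterministic simulator that generates toy genomes,
    annotations, fusion calls and spliced alignments with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    rtracklayer,
    GenomicRanges,
    GenomicAlignments,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
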