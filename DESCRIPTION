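Package: tnCIS
Title: Common Insertion Site Detection for Transposon Insertional Mutagenesis Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of barcoded transposon junction-fragment reads
    from forward genetic screens. Demultiplexes and trims reads, maps genomic
    fragments with an iterative prefix schedule of decreasing length and
    mismatch allowance, resolves insertion orientation, bins insertions into
    100-bp regions with a clonality read-fraction cutoff, detects Common
    Insertion Sites (CISs) by Poisson scan statistics with Bonferroni
    correction under three event-counting schemes (inserts, libraries,
    regions), and tests CIS-phenotype and CIS-CIS associations with Fisher's
    exact test. Includes a synthetic-screen simulator with known truth for
    validation, and BED/WIG/TSV track export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
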