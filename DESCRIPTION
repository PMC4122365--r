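Package: poolscan
Title: Fixed-Difference Variant Scanning for Pooled Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pooled-sequencing data from experimental
    evolution. Implements quality-masked evaluable-locus selection,
    fixed-difference SNP and small-indel calling between a control pool and
    two replicate selected pools, reciprocal-replicate false-discovery-rate
    estimation, homopolymer flagging, variant-to-extended-gene annotation
    with coding-effect classification, polymorphism-density statistics, and
    hypergeometric pathway enrichment. A Wright-Fisher synthetic-data
    generator emulates the evolve-and-resequence design (isogenic founder
    lines, replicate selected populations, sex-balanced pools, short-read
    depth and quality fields) and provides truth tables for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
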