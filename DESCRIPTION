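Package: circat
Title: Detection and Analysis of Circular RNAs of All Types from
    Paired-End RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects circular RNAs (circRNAs) of all structural types --
    canonical back-spliced, partial and complete interior, and intergenic
    -- from stranded paired-end RNA-seq reads without using splice-signal
    information.  Linearly mappable reads are discarded, anchors extracted
    from the unmapped remainder are placed in reversed orientation, and
    the back-fusion split point is resolved exactly, with a mate-pair
    containment constraint.  Downstream analyses include junction-feature
    characterization (short homologous sequences, complementary flanks,
    GT-AG annotation), spliced-reads-per-billion-mappings normalization,
    rank-sum differential expression with exact tie-aware enumeration,
    and circRNA-miRNA-mRNA competing-endogenous-RNA association.  A fully
    seeded synthetic-data generator produces toy genomes, annotations,
    planted circRNA truth sets and paired-end reads for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
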