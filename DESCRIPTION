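Package: regap
Title: Reference-Guided Re-Assembly of Repeat-Broken Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closes repeat-induced gaps in reference-guided (re-sequencing)
    genome assemblies from long single-end pyrosequencing-style reads.
    Maps reads to the reference, calls anchor contigs from the pileup,
    discards contigs shorter than a configurable gap size and marks their
    coordinates (plus uncovered intervals) as repeat regions, re-assembles
    every repeat region iteratively from its locally mapped reads with a
    greedy overlap-layout-consensus strategy seeded at the flanking
    anchors, and stitches anchors and repeat-resolved contigs into final
    gap-closed contigs by end-overlap consensus. Includes a planted-repeat
    genome and pyrosequencing read simulator with ground truth, NG(X)/LG(X)
    and gap-filling assembly metrics, and gap-size / coverage sweep
    harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
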