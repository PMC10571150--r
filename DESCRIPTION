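Package: epimark
Title: Integrative Analysis of Histone-Mark Redistribution and Transcriptional Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A count-level pipeline linking histone-modification ChIP-seq
    redistribution to transcriptional modulation. Calls differential peaks and
    differentially expressed genes with a negative-binomial Wald test under
    TMM normalization and Benjamini-Hochberg FDR control, classifies peaks as
    promoter or enhancer using promoter-capture Hi-C style interaction maps,
    tests the peak-gene association with Fisher's exact test, builds
    activation-status matrices of regulatory elements from H3K27ac gains and
    losses, calls broad H3K9me2 heterochromatic domains (KDDs) from binned
    coverage and tests DEG proximity to changed domains by permutation, and
    provides MDS sample-similarity and hypergeometric over-representation
    utilities. Ships a fully labelled synthetic-data generator so every stage
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    edgeR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
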