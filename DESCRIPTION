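Package: natpairs
Title: Sense/Antisense Pair Analysis for Paired Tumor-Normal Stranded RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds pairs of protein-coding genes and their cis natural
    antisense transcripts (ncNAT/PCT pairs) from a GTF annotation, quantifies
    their joint expression in paired tumor and adjacent non-malignant samples,
    and selects deregulated pairs by three complementary methods: differential
    Spearman correlation with a Fisher-z test, paired differential expression
    of the antisense, and the variation of the antisense-to-sense read-count
    ratio (varRatio). Selected gene lists are screened for enrichment in
    survival-associated genes against random-control distributions. A
    synthetic-data generator with planted effects supports end-to-end testing
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
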