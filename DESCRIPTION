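Package: agoscan
Title: Small RNA Classification, Argonaute-IP Enrichment, and Secondary
    siRNA Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting microRNA-triggered secondary siRNA
    production in C. elegans-style small RNA sequencing data. Provides a
    seeded synthetic-data generator emulating Argonaute
    immunoprecipitation and genotype-conditioned total small RNA
    libraries; exact-match read mapping and twelve-class read annotation
    (siRNA, repeat RNA, known microRNA, 21U-RNA, scRNA, snRNA, snoRNA,
    non-hairpin region, tRNA, rRNA, sense RNA, other); library scaling
    and log2 enrichment/depletion statistics; per-locus secondary siRNA
    signature scoring (antisense polarity, 5' triphosphate/TAP
    dependence, exon restriction, 3' coverage gradient); perfect
    complementarity microRNA target-site scanning with a trans-action
    hit analysis; and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stringi,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
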