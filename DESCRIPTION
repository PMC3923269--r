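Package: synescreen
Title: Sequence Analysis for Sequential-Enrichment Screens of Synthetic
    Cis-Regulatory Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sequential-enrichment (Pol II ChIP) screens
    of randomized synthetic cis-regulatory element (SynE) libraries, from
    barcoded paired-end reads to candidate elements. Implements demultiplexing
    and positional extraction of the two 12-nt random cores from fixed flanks,
    non-redundant count tables, frequency-guided Hamming-distance-1 clustering
    with cluster representatives and cumulative frequencies, k-mer (5-7 nt)
    enrichment ratios of ChIP samples against their source sub-library,
    coupled left/right core extraction with MEME-ready FASTA export, and
    IUPAC degenerate motif annotation against a PLACE-style motif table. A
    truth-tracked simulator generates barcoded paired-end reads with
    planted-motif enrichment for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
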