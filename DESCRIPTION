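Package: mosaiclr
Title: Single-Sample Mosaic SNV Calling from Linked-Read Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects post-zygotic (mosaic) single-nucleotide variants from a
    single linked-read whole-genome sequencing sample. Barcoded short reads are
    grouped into long-fragment molecules, each molecule is assigned to a
    haplotype using phased germline heterozygotes, and candidate sites are
    scored by a sample-specific random forest trained on haplotype-aware
    synthetic spike-in variants, with germline variants as negatives. Includes
    a linked-read simulator with known germline and mosaic truth, an
    evaluation harness with allele-fraction-stratified precision and recall,
    and an orthogonal deep-coverage validation rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    tibble,
    dplyr,
    data.table,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    methods,
    jsonlite,
    digest,
    ranger,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
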