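Package: spliceMPRA
Title: Splicing Reporter Assay Design, Quantification and Splice-Disrupting
    Variant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for massively parallel splicing reporter
    (Vex-seq style) experiments: design of barcoded oligonucleotide pools
    from gene models and SNPs, plasmid-library barcode quality control,
    UMI-deduplicated percent-spliced-in (PSI) quantification from
    junction-spanning read pairs, statistical calling of splice-disrupting
    variants (SDV), benchmarking of splice-effect predictors (ROC/AUC,
    threshold scans), rule-based transcript consequence and NMD
    classification, and GWAS post-processing (candidate filtering, QTL
    interval definition). A synthetic-data generator with known ground
    truth makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    vcfR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
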