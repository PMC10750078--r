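Package: gkmvar
Title: Gapped k-mer SVM Prioritization of Noncoding Regulatory Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for prioritizing noncoding disease
    variants in regulatory DNA. Trains a gapped k-mer support vector
    machine on transcription-factor-bound sequences, scores all canonical
    oligomers, reconstructs binding motifs from top-weighted k-mers,
    computes deltaSVM allele-effect scores, filters and expands GWAS
    association catalogs through enhancer/footprint intersection, linkage
    disequilibrium proxies and tissue eQTL joins, and quantifies
    electrophoretic mobility shift assays with one-site specific-binding
    fits. Includes a deterministic synthetic-data generator that emulates
    every input so the full pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    withr,
    kernlab,
    minpack.lm,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
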