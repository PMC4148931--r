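Package: hypoxamir
Title: Hypoxia-Regulated Small RNA Sequencing Analysis with Planted Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end small RNA deep-sequencing analysis for two-condition
    (normoxic versus hypoxic) libraries: 3' adapter trimming, 16-35 nt length
    filtering and read collapsing into unique tags; hierarchical elimination
    annotation against mature miRNA, ncRNA, piRNA and rRNA/mRNA databases and
    the genome; TPM/RPKM normalization and fold-change differential calling;
    isomiR cataloguing of 5'/3' end variants with non-templated additions;
    novel miRNA hairpin discovery by weighted base-pair-maximization folding
    with stem-placement rules; hypoxia response element (RCGTG) scanning of
    5 kb promoter regions; and a seed-match plus multi-program consensus
    target combiner. A seeded synthetic-data module generates the reference
    bundle and FASTQ libraries with full planted ground truth so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
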