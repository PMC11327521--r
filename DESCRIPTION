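Package: ncatsr
Title: Analysis of Nanopore Cas9-Targeted Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, desk-scale pipeline for nanopore Cas9-targeted
    sequencing (nCATS) of a fusion-gene locus: on-target enrichment QC with
    Cas9 cut-site and PAM-motif diagnostics, split-read detection and
    clustering of inter-locus fusion breakpoints, a transparent
    genotype-likelihood SNV caller with multi-caller concordance analytics,
    and per-read CpG 5-methylcytosine aggregation with bisulfite-amplicon
    concordance. Ships a seeded simulator of Cas9-targeted long reads
    (fusion alleles, planted variants, methylation profiles, truth
    alignments) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    tools,
    utils,
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
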