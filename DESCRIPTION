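Package: credentor
Title: Cryptic Retrotransposon-Associated Transcript Discovery and
    Hypoxia-Methylation Cohort Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies de-novo-assembled transcripts into cryptic,
    retrotransposon-associated transcripts, associates them with
    hypoxia-inducible-factor (HIF) binding, and quantifies their
    expression from uniquely mapped reads. Provides HRE (RCGTG) motif
    scanning, presence/absence ChIP peak calling against local
    background, permutation-based repeat-class enrichment with
    excluded-region handling, double-stranded-RNA potential flags,
    and tumor-cohort statistics: hypoxia metagene clustering,
    promoter-methylation stratification, cytolytic activity, and a
    negative-binomial hypoxia-by-methylation interaction test. A
    synthetic-data module generates truth-annotated genomes, peaks,
    counts and methylation tables so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    MASS,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
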