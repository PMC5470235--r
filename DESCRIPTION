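Package: tespectrum
Title: Transposable-Element Activation, Chimeric Transcripts, and DNA
    Methylation across a Spectrum of Pluripotent States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for mapping a spectrum of embryonic stem
    cell states from bulk sequencing summaries: quantification of
    transposable-element (TE) family expression with an explicit multimapper
    policy, detection of TE-to-gene chimeric transcripts from splice
    junctions in spliced alignments, pairwise negative-binomial differential
    expression with a principal-component ordering of states, and weighted
    DNA-methylation levels over genomic features and imprints from shallow
    whole-genome bisulfite CpG reports. Includes a fully deterministic
    synthetic-data generator that plants every signal the pipeline detects,
    so all stages are testable without access to real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomicAlignments,
    Rsamtools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
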