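Package: tandemdiv
Title: Divergence Analysis of Tandem Gene-Family Duplicates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects tandem arrays of gene-family members from genome
    annotation, classifies duplicates as ancestral or lineage-specific using
    a two-species gene tree, and quantifies sequence (Pi, Nei-Gojobori
    Ka/Ks), structural (intron and motif architecture), and expression
    (RPKM thresholding, pair correlation, delta-delta-Ct) divergence
    between duplicate classes. Includes a two-species gene-family simulator
    with known duplication history for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    phangorn,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
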