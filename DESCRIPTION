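Package: substrainr
Title: Substrain-Exclusive Variant Discovery and Regulatory Effect Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparing whole-genome variant call
    sets from two closely related inbred lines (substrains) sharing one reference
    genome. Implements quality, alt-allele-depth and inter-variant spacing filters
    with line-exclusivity calling; assignment of exclusive variants to genes and
    region classes (coding, non-coding genic, regulatory, intergenic) with
    nearest-gene attribution; candidate-gene triage against gene sets and an
    expression table; and allele-aware prediction of transcription-factor
    binding-site gain or loss by position-weight-matrix scanning, together with a
    splice-window assessment for intronic variants. Ships a deterministic
    synthetic-study generator with a per-variant ground-truth ledger for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    vcfR,
    Biostrings,
    IRanges,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
Config/testthat/edition: 3
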