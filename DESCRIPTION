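Package: polyzf
Title: Comparative Evolution of Poly-Zinc-Finger Transcription Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for comparative analysis of
    Cys2-His2 zinc finger (C2H2-ZF) transcription factors across a clade of
    species with 1-to-1 orthology to a reference. Calls C2H2-ZF domains from
    HMMER hit tables or a structural regular expression, selects representative
    isoforms, assembles tandem arrays with canonical-linker classification,
    builds reference-anchored 1-to-1 orthogroups with duplication/loss
    reconciliation of gene trees against a species tree, classifies domain
    loss/gain and DNA-contacting-residue divergence, runs three
    functional-constraint analyses (clade support, evolutionary-rate ranks,
    fixation versus polymorphism) plus folded site-frequency spectra, predicts
    per-domain binding specificities with a pluggable predictor and a
    consensus-confidence filter, and quantifies binding-site turnover in
    aligned promoters with an exact-p-value motif scanner. A fully
    ground-truth-labeled synthetic data generator makes the whole pipeline
    hermetic and testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    phytools,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
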