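Package: rabscreen
Title: Transcriptional Deregulation Screening of Rab-Family Gene Sets in
    Stratified Tumor Subgroups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects transcriptional deregulation of a curated family of Rab
    GTPase genes and Rab-interacting genes across stratified bladder tumor
    subgroups. Implements the SAM two-class unpaired permutation test
    (relative difference with automatic exchangeability-constant estimation
    and permutation-based q-values), fold-change/q-value deregulation calls,
    stromal filtering against cancer cell-line and normal urothelial culture
    profiles, pathway-specificity testing, exact binomial cluster enrichment,
    and marker-correlation association with proliferation and urothelial
    differentiation markers. Ships a curated gene catalog, a synthetic-cohort
    simulator with planted effects for end-to-end testing, and a pipeline
    orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
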