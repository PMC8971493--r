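Package: mirisk
Title: Blood miRNA Survival Signatures for Immunotherapy Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovery and evaluation of blood-based microRNA prognostic
    signatures for overall survival under PD-1 inhibitor therapy. Implements
    Cox proportional-hazards fitting (Efron and Breslow tie handling),
    Kaplan-Meier estimation, the log-rank test, Harrell's concordance index
    and IPCW time-dependent ROC analysis; a univariable-filter plus
    cross-validated sequential forward selection discovery pipeline with
    median-cutpoint risk stratification, including the published five-miRNA
    miRisk score; cell-of-origin deconvolution of whole-blood miRNA profiles
    against a sorted-cell atlas; qRT-PCR delta-delta-Ct concordance and
    blocked-library efficiency statistics; and a seeded synthetic cohort
    generator emulating whole-blood small RNA-seq data with planted survival
    effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
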