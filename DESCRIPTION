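Package: eadiag
Title: Diagnostic Feature Analysis for Episodic Ataxia Types 1 and 2
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distinguishing episodic ataxia type 1 (EA1, KCNA1)
    from type 2 (EA2, CACNA1A) using curated per-subject phenotype records.
    Provides a tri-state (present/absent/unknown) cohort data model with CSV
    and JSON serialisation, attack-metric binning and trigger taxonomy
    mapping, variant functional-group annotation (loss of function, gain of
    function, haploinsufficiency), per-feature diagnostic accuracy statistics
    (sensitivity, specificity, ROC AUC with Hanley-McNeil confidence
    intervals, chi-square and Fisher exact association tests), ROC/AUC based
    feature selection, a sequential rule-based diagnostic classifier, and a
    synthetic cohort simulator for exercising the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
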