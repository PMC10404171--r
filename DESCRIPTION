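Package: protreact
Title: Peptide-Depletion Reactivity Analysis for Skin Sensitization Hazard
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of in chemico skin-sensitization reactivity assays based
    on percent peptide depletion. Converts raw plate-reader signals (absorbance
    or fluorescence) into cysteine and lysine percent depletion via
    reference-control normalisation, derives classification cut-offs by ROC
    analysis with Youden's J, applies binary hazard prediction models to a
    bundled 106-chemical benchmark dataset with human potency categories,
    computes confusion-matrix performance metrics, and compares two assays
    (a spectrophotometric ProtReact-style assay versus the HPLC-based direct
    peptide reactivity assay) chemical by chemical, including per
    mechanistic-domain tallies. Includes simulators for raw plate runs and
    labeled depletion populations so every pipeline stage is testable without
    laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
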