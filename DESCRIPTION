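Package: uromarker
Title: Biomarker Discovery from Urine Metabolomics Peak Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Marker discovery for two-group GC-MS urine metabolomics peak
    tables. Implements a leave-one-out cross-validated two-phase screen
    (Bonferroni-corrected Wilcoxon rank-sum test plus a detection-frequency
    filter), per-marker classifying thresholds selected by Youden's J,
    a ridge-stabilised logistic-regression marker panel evaluated on an
    independent cohort, and PCA / OPLS-DA separation diagnostics with
    cross-validated Q2. Includes a zero-inflated log-normal profile
    simulator for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
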