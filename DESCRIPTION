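Package: ucdcoder
Title: Neural Underlying-Cause-of-Death Coding from Death Certificates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated selection of the underlying cause of death
    (UCD) from ICD-10 coded death certificates. Provides the certificate data
    model and padded code-grid encoding, a seeded synthetic certificate
    simulator with a deterministic rule-based coding oracle (including
    Part-II promotion, neonatal and year-dependent rules, and rejects), a
    convolutional probabilistic coder over shared code embeddings with
    additive demographic embeddings trained by Adam on cross-entropy, a
    reject-aware evaluation suite (bootstrap confidence intervals,
    per-chapter error analysis, top-k accuracy, confidence calibration), and
    temporally harmonized batch recoding with cause-group time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
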