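Package: conformalpr
Title: Conformal Risk Control and Probability Calibration for Protein Retrieval
Version: 0.1.0
Authors@R:
    person("conformalpr", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Model-agnostic calibration of raw protein search scores
    (similarity or distance, from any homology or function model) into
    retrieval sets with user-specified risk guarantees and into calibrated
    match probabilities. Implements conformal risk control for monotone
    set losses (false negative rate, hierarchical EC/SCOPe mismatch),
    Learn-then-Test threshold selection for non-monotone losses (false
    discovery rate), Venn-Abers/isotonic probability calibration, baseline
    selectors (max-separation, empirical p-value), Kneedle elbow detection,
    structural-prefilter evaluation, exchangeability diagnostics, and seeded
    synthetic-data generators so every calibration path is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
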