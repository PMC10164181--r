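Package: shiftbench
Title: Benchmarking Predictive-Uncertainty Generalisation Under Distribution Shift
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well multiclass classifiers generalise
    their predictive uncertainty from development (in-distribution) data to
    production (shifted) data. Implements confidence and Shannon-entropy
    uncertainty statistics, expected calibration error (ECE), F1-retention
    curves and their area (F1-AUC), F1-uncertainty curves, and the area
    between the development and production curve (ADP) with bootstrap
    confidence intervals. Ships four controlled classifier constructions
    sharing one residual-network architecture (a pointwise baseline,
    Monte Carlo dropout with a heteroscedastic Gaussian logit head, a
    bi-Lipschitz variant using spectral normalisation, and a deep ensemble),
    a synthetic strata generator emulating batch shift, metastatic signature
    blending and unseen classes, and an orchestrator that runs the full
    development-to-production benchmark and reports the results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
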