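Package: hsrocpoint
Title: Summary Points from the Hierarchical Summary ROC Model for
    Diagnostic Test Accuracy Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits the Rutter-Gatsonis hierarchical summary receiver
    operating characteristic (HSROC) model to per-study diagnostic 2x2
    tables by Markov chain Monte Carlo and reports the posterior point
    estimate and 95 percent credible interval of sensitivity at a
    user-fixed specificity (or specificity at a fixed sensitivity).
    Includes delimiter-separated data import with validation, split
    R-hat and effective-sample-size convergence diagnostics, posterior
    summary tables with CSV export, density and trace plots, a
    summary-of-findings row for GRADE-style tables, and a one-command
    pipeline mirroring an interactive calculator workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
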