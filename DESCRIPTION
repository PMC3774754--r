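Package: survsig
Title: Survival Evaluation of Gene-Expression Signatures with Risk Groups
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Evaluates gene-expression signatures against censored clinical
    outcomes. Computes a Cox-based or user-weighted prognostic index,
    stratifies samples into risk groups by quantile splits or by
    log-rank-optimized split points, and reports survival statistics:
    Kaplan-Meier curves, k-sample log-rank tests, hazard ratios, Harrell's
    concordance index and time-dependent ROC curves. Includes identifier
    resolution against NCBI gene_info annotation, probe-to-gene collapsing,
    expression preprocessing (log2, quantile normalization), a multi-cohort
    merging procedure that equalizes per-cohort probeset means while
    preserving per-cohort spread, a proportional-hazards fixture simulator,
    publication-style reporting, and a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    limma,
    MASS
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
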