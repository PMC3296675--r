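Package: descmeta
Title: Meta-Analysis of Descriptive Single-Group Outcomes with Forest Plots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fixed-effect and DerSimonian-Laird random-effects meta-analysis
    for descriptive (single-group) data such as rates and prevalences:
    per-study effect sizes and standard errors from raw event counts or from
    pre-computed confidence intervals, inverse-variance pooling, Cochran's Q
    and I-squared heterogeneity statistics, the between-study variance
    moment estimator, and leave-one-out sensitivity analysis. Includes a
    forest-plot builder that renders study rows with asymmetric error bars,
    a summary diamond and a vertical summary reference line to SVG or PNG,
    a command-line interface over CSV study tables, and a synthetic-study
    generator for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    xml2,
    optparse,
    withr
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
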