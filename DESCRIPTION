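Package: dvmeth
Title: Differential Variability Analysis for DNA Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Feature selection for epigenome-wide studies based on
    differential variability (DV) rather than differential means.
    Implements the iEVORA algorithm (Bartlett's test with q-value FDR
    control, followed by re-ranking of significant sites by a
    differential-methylation t-statistic) together with four comparator
    DV tests (plain Bartlett, an empirical-Bayes Levene-type test on
    M-value deviations, a robust joint mean/variance score test, and a
    nested Gaussian location-scale likelihood-ratio scheme), a
    moderated-t differential-mean baseline, Storey-type q-value
    estimation, a beta-mixture simulator of the three canonical DV
    types, a DV-type taxonomy classifier, a Monte-Carlo sensitivity and
    true-FDR benchmark, and a progression positive-predictive-value
    evaluation on independent validation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), limma, jsonlite, withr
Config/testthat/edition: 3
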