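Package: panelMR
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonizes GWAS summary-statistics tables into oriented
    exposure-outcome panels and estimates causal effects with the
    inverse-variance-weighted, MR-Egger, weighted-median and multivariable
    inverse-variance-weighted estimators. Includes instrument diagnostics
    (explained variance, cross-trait and LD-proxy exclusion, stepwise
    Cochran-Q heterogeneity filtering), assessment of the no-measurement-error
    assumption via the I-squared-GX statistic with simulation-extrapolation
    (SIMEX) correction of the MR-Egger slope, analytic power calculations for
    two-sample designs, and a synthetic summary-statistics generator with
    known ground truth for validation. A bidirectional pipeline driver runs
    every estimator in both causal directions and writes a tabular report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
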