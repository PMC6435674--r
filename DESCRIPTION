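Package: nwdose
Title: Factorial Nitrogen-by-Water Dose-Response Analysis of RNA-Seq Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to classify genes by their response to nitrogen amount
    (N-moles), water volume (W), nitrogen concentration (N/W) and the
    synergistic N-by-W interaction in factorial dose experiments.
    Implements per-gene negative-binomial generalized linear models with
    backward model simplification into simplified model forms, an N vs N/W
    coefficient weight statistic, cubic-spline time-course differential
    expression with per-timepoint fold-change binning, field-side
    classification with a genotype covariate and interaction-sign binning,
    eigengene construction with permutation-based phenotype association,
    Monte-Carlo gene-set overlap tests, and a negative-binomial synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    splines,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
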