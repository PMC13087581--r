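Package: plategrowth
Title: Growth-Curve Analysis for Nephelometric and Spectrophotometric Yeast Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of liquid-culture microbial growth assays
    measured on plate readers, in nephelometric (RNU) or spectrophotometric
    (OD600) mode. Reads long-format plate time series with a well layout,
    applies blank correction, negative-control background normalization and a
    four-step preprocessing chain (pre-minimum clamping, initial-value
    rebasing, Savitzky-Golay smoothing, technical-replicate averaging), fits a
    logistic population growth model by bounded least squares with a
    data-driven initialization, derives maximum-slope time, lag time and
    maximum growth rate, and compares construct groups with an exact
    Mann-Whitney U test. Includes a plate simulator with per-well ground truth
    that reproduces the replicate hierarchy, blank baselines, background
    growth controls and the nephelometric peak-then-decline artifact, so the
    whole pipeline can be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
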