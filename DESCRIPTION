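Package: bloodrisk
Title: Self-Supervised Health-Risk Scoring from Complete Blood Count Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for screening multi-analyte blood panels (HTC, HGB,
    WBC, PLT, MPV): min-max normalization, multi-dimensional elimination of
    records whose analytes all fall inside a mean +/- a*sd band,
    self-weighting of the remaining abnormal records onto a -100..+100
    percent risk scale, interval-balanced selection of training data, and a
    norm-power basis regression model fitted with four learners (batch least
    squares, per-sample gradient descent, norm-constrained per-sample least
    squares, and shuffled complex evolution). Includes a synthetic panel
    generator for end-to-end testing and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
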