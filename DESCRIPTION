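Package: chemoRank
Title: Dose-Response Curve Classification and Chemosensitivity Ranking for
    Primary-Culture Viability Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Classifies drug dose-response curves from primary-culture
    microplate viability assays (WST absorbance at 450 nm) into six shape
    families (logistic, hyperbolic, straight, exponential, linear,
    noise-dominant) by bounded multi-start nonlinear least squares and
    small-sample information-criterion model selection; extracts absolute
    GI50 from logistic fits; ranks drugs within a specimen by the log-ratio
    margin between peak plasma concentration (ppc) and GI50; flags
    resistance from hyperbolic patterns; aggregates cohort-level informative
    rates, curve-type frequency tables and Up/Stable/Down outcome response
    fractions; and generates seeded synthetic assay plates with the
    statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
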