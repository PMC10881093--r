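Package: cowintake
Title: Prediction and Validation of Dry Matter Intake in Beef Cows
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting daily dry matter intake (DMI) of
    nonlactating and lactating beef cows from shrunk body weight and diet
    net energy for maintenance (NEm), and for validating any intake
    equation against observed treatment means. Implements eight closed-form
    prediction equations (three historical nonlactating equations, three
    lactating counterparts, and two pooled-stage models fit on recent
    confinement data), observed-versus-predicted unity-line regression with
    tests of intercept = 0 and slope = 1, root mean squared deviation,
    Theil decomposition of the squared sum of prediction error into bias,
    slope, and random components, studentized-residual outlier screening,
    refitting of the metabolic-scaled energy intake (NEMI) and direct DMI
    models with interaction pruning, recursive path analysis with
    standardized direct and indirect effects, and a truncated-normal
    synthetic treatment-mean generator so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
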