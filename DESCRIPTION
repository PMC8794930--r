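Package: strokecea
Title: Cost-Effectiveness of Supplemental Short-Protocol Brain MRI for
    Minor Stroke Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing
    "no additional imaging" against "additional short-protocol MRI" for
    the detection of minor strokes in emergency patients with negative
    non-contrast head CT. A diagnostic decision tree feeds a 30-year,
    seven-state Markov cohort model with discounted cost and QALY
    accumulation; incremental cost-effectiveness and dominance are
    evaluated at a stated willingness to pay. Includes deterministic
    (tornado, ICER-versus-parameter) and probabilistic (Monte Carlo,
    CEAC) sensitivity analyses, parametric Gompertz-Makeham life-table
    generation, and an independent individual-level microsimulation for
    validating the cohort engine.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
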