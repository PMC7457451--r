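Package: refersdt
Title: Signal Detection Analysis of Urgent Cancer Referral Decisions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for signal-detection analyses of repeated clinical referral
    decisions, as used in vignette studies of general practitioners deciding
    whether to refer patients urgently for suspected cancer. Computes
    per-responder discrimination (d') and response bias (criterion c) from hit
    and false-alarm rates with the 0.5 count correction, estimates the same
    quantities jointly with covariate effects via (mixed-effects) probit
    regression on trial-level decisions, relates the indices to organizational
    performance measures, tests cross-task stability, fits a
    predictor-mediator-outcome mediation model with a bootstrap confidence
    interval for the indirect effect, and runs Monte Carlo power analyses for
    indirect effects. A synthetic-data generator reproduces the statistical
    structure of a 252-responder by 48-vignette study so the whole pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
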