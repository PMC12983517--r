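Package: vpdx
Title: Automated Scoring and Longitudinal Analysis of Virtual-Patient
    Diagnostic Reasoning Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for rubric-driven assessment of clinical reasoning in
    staged virtual-patient encounters. Scores student interaction traces
    (differential diagnosis snapshots, diagnostic-justification assignments,
    test ordering rounds, stage navigation) against expert scorecards,
    detects five classes of cognitive error (premature closure, failure to
    rule out, confirmation bias, anchoring, search satisficing) with
    rule-based algorithms, simulates multi-school learner cohorts with
    latent skills, practice effects and AR(1) within-student dependence,
    and analyses the resulting longitudinal score tables with clustered
    marginal (GEE) logistic models, mixed-effects learning curves and
    correct-versus-misdiagnosed group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    lme4,
    dplyr,
    tidyr,
    tibble,
    ggplot2,
    rlang,
    e1071
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
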