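Package: postopwindow
Title: Join-Point Hazard Estimation of the Postoperative Fatality Window
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the postoperative fatality window from
    registry-style cohort data using a join-point hazard model: the daily
    death rate declines linearly from an acute-phase rate (anchored at
    postoperative day 3) to a join point, the phase shift time, after which
    it stays at a constant background rate until the administrative
    follow-up horizon.  Provides maximum-likelihood fitting with
    profile-likelihood confidence intervals, likelihood-ratio tests for
    comparing hazard structure across patient groups, model-free hazard
    diagnostics (daily empirical hazard, Nelson-Aalen cumulative hazard
    with pointwise intervals, a late-window constancy check), a cohort
    pipeline for elective colorectal-resection registry analyses
    (exclusions, categorisation, descriptive tables, subgroup fits,
    stage-IV sensitivity analysis), and a seeded synthetic registry-cohort
    generator so the whole workflow runs without registry access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
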