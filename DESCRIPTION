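Package: darecea
Title: Cost-Effectiveness of Digital Ano-Rectal Examination Screening for Anal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A probabilistic Markov cohort model evaluating regular digital
    ano-rectal examination (DARE) screening for anal cancer in men who have sex
    with men living with HIV. Implements the natural-history cohort engine with
    time-since-diagnosis tunnel states, Weibull calibration of stage-specific
    relative survival, Bayesian post-test screening arithmetic, lifetime cost and
    QALY accumulation with half-cycle-corrected discounting, ACER/ICER efficiency
    frontier analysis with strict and extended dominance, one-way sensitivity
    analysis, and second-order Monte Carlo probabilistic sensitivity analysis
    with cost-effectiveness acceptability curves. Includes a synthetic-data
    module generating age-indexed incidence and mortality schedules and
    stage-specific survival datasets so the full pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
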