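Package: palboCEA
Title: Markov Cohort Cost-Effectiveness Model of Palbociclib plus
    Fulvestrant in HR+/HER2- Advanced Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-state (progression-free, progressed, dead) Markov cohort
    model evaluating palbociclib plus fulvestrant against placebo plus
    fulvestrant as second-line therapy for hormone-receptor-positive,
    HER2-negative advanced breast cancer from the Chinese healthcare system
    perspective. Provides parametric survival extrapolation of
    progression-free and overall survival (six families, AIC/BIC selection),
    per-cycle transition probabilities, half-cycle-corrected discounted cost
    and QALY accumulation, incremental cost-effectiveness ratios, one-way
    deterministic sensitivity analysis with tornado ranking, and Monte Carlo
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. Ships the published model inputs as a configuration file and a
    synthetic-data generator for censored event times emulating digitized
    Kaplan-Meier data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    survival,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
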