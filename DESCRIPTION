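Package: stopbayes
Title: Bayesian Anticipation Modelling for the Stop-Signal Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying proactive control in the stop-signal task.
    Implements a dynamic Bayesian belief model that estimates the
    trial-by-trial probability of an impending stop signal from the go/stop
    history, a staircase-tracked task simulator driven by the race model,
    race-model estimation of the stop-signal reaction time (SSRT), the
    sequential-effect statistic linking anticipation to go reaction time,
    first-level GLM analysis of region-of-interest BOLD time series with
    canonical HRF regressors, ordered parametric modulators, high-pass
    filtering and AR(1) prewhitening, and second-level trait regressions
    with gender slope comparisons. A synthetic-cohort generator reproduces
    the behavioral and trait statistics of a typical adult cohort so that
    the complete analysis chain can be exercised and validated end to end
    without access to raw neuroimaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
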