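Package: wellcast
Title: Predicting Daily Athlete Recovery from Training, Diet, Sleep and HRV Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Models morning perceived recovery status and day-to-day change
    in log-transformed heart-rate variability (Ln rMSSD) of endurance
    athletes from daily training, dietary, sleep, wellness and autonomic
    logs. Provides a synthetic multi-athlete cohort generator with known
    generative coefficients, session-RPE training-load and rolling-window
    feature engineering (monotony, strain, exponentially weighted moving
    averages), lag-based unfolding of the daily time series into
    independent observations, group models validated by
    leave-one-subject-out cross-validation against an intercept-only
    baseline, individualized models selected by repeated k-fold
    cross-validation with bootstrap accuracy metrics, permutation
    importance and partial-dependence interpretation, and a mixed-model
    comparison of model families across athletes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    generics,
    ggplot2,
    glmnet,
    lme4,
    emmeans,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    caret,
    e1071,
    xgboost,
    nnet,
    withr
Config/testthat/edition: 3
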