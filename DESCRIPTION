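Package: cgmforecast
Title: Hybrid Transformer-LSTM Forecasting for Continuous Glucose Monitoring
Version: 0.1.0
Authors@R:
    person("CGM", "Forecast Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for short-horizon blood-glucose forecasting from
    continuous glucose monitoring (CGM) traces sampled every five minutes.
    Provides a documented CSV dialect with gap-aware regularization, a
    calibrated synthetic CGM cohort simulator (circadian baseline, meal
    excursions, autocorrelated sensor noise, signal-loss gaps), leak-free
    sliding-window supervised dataset construction, a hybrid Transformer
    encoder + LSTM forecaster together with five recurrent baselines
    trained by a package-internal reverse-mode autodiff engine, per-horizon
    mean-squared-error evaluation with residual normality diagnostics, and
    genetic hyperparameter optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
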