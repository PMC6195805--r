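Package: wristload
Title: Wrist-Worn Accelerometry Metrics of External Training Load in Runners
Version: 0.1.0
Authors@R: person("wristload", "maintainers", email = "maintainers@wristload.dev", role = c("aut", "cre"))
Description: Processes raw wrist-worn triaxial accelerometer data into
    calibrated 5-second ENMO epochs, computes daily training-load metrics
    (average acceleration, most active 30 minutes, minutes at or above
    400 mg, 50-mg intensity-bin minutes and the WL400-4000 workload
    composite), classifies running versus nonrunning days by ROC-derived
    optimal cutpoints with leave-one-participant-out cross-validation,
    and quantifies convergent validity of accelerometer metrics against
    self-reported training-log criteria (miles, duration, session-RPE
    training load) by linear regression. Includes a synthetic-cohort
    generator emulating a running cohort with mixed training days so the
    whole pipeline is testable without real data, plus a seedable
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
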