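Package: tremorforce
Title: Quantification of Action Tremor from Finger-Force Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of fingertip force recordings used to
    detect, quantify and classify action tremor. Provides seeded generators
    for protocol-driven strain-gauge measurements, whole study cohorts and a
    motor-driven validation rig; preprocessing (percentile outlier repair,
    zero-phase 3.5-7.5 Hz band-pass, hold-window extraction); single-segment
    periodogram statistics including the dominant frequency, peak power and
    the scale-free peak power proportion used as a measurement-validity
    criterion; a 41-point resampled amplitude-spectrum feature pipeline with
    four reference classifiers under stratified cross-validation; and study
    harnesses for encoder-vs-gauge frequency agreement (two-sample z-test)
    and repeated-measurement threshold sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
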