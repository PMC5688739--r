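Package: cagewatch
Title: Simulation and Analysis of Microwave Doppler Home-Cage Activity
    Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with event logs from microwave Doppler
    (X-band radar) home-cage activity monitors. Provides a synthetic-data
    generator for circadian mouse activity (inhomogeneous Poisson events
    with per-day photoentrainment dynamics) and analog-clock validation
    streams; a model of the detector-to-logger chain (retriggerable
    pulse extension, interrupt-driven logging with dead time, inter-cage
    crosstalk and shielding) with a comma-separated log format;
    inter-event interval statistics, histograms and autocorrelation-based
    rhythm detection; actogram construction, daily and windowed activity
    summaries, light-cycle modulation statistics and circular
    cross-correlation phase-shift estimation; a frame-differencing video
    motion scorer with method-comparison statistics; and far-field
    microwave dosimetry estimates (EIRP conversion, power density, duty
    cycle).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
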