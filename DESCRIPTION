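Package: kinagree
Title: Agreement Analysis for Paired Motion-Capture Joint-Angle Waveforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Method-comparison tools for paired joint-angle waveforms recorded
    simultaneously by a test (markerless) and a reference (marker-based)
    motion-capture system during change-of-direction running. Implements
    stance-phase preprocessing (force-threshold stance detection, zero-phase
    Butterworth filtering, resampling, 101-point time normalization, discrete
    event extraction), extended Bland-Altman analysis for repeated measures via
    linear mixed-effects models (bias line, adjusted-SD limits of agreement
    with confidence intervals, assumption checks), bootstrapped functional
    prediction bands for difference waveforms with cluster dependence, a
    stratified three-level study pipeline with speed-tertile categorization,
    and a synthetic paired-trial generator with a controllable difference
    structure for validation by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
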