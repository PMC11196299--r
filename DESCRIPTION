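Package: piezosleep
Title: Sleep Apnea Screening from Piezoelectric Sheet Micromotion Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unobtrusive home sleep apnea testing from a single-channel
    micromotion signal recorded by a piezoelectric rubber sheet sensor placed
    under the bedsheet. The signal is decomposed into respiratory, body
    movement, and ballistocardiogram components by zero-phase band-pass
    filtering; respiratory events are detected as dips of a fast 95th
    percentile envelope of the log respiratory amplitude below a slow
    envelope, yielding a respiratory event index (REI). Heartbeat intervals
    extracted from the ballistocardiogram are scored for cyclic variation of
    heart rate (CVHR), yielding its hourly frequency (Fcv). Includes
    grid-search calibration of the detection parameters against a reference
    apnea-hypopnea index, ROC-based severity classification metrics, and a
    seeded synthetic-data generator with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
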