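Package: peristartle
Title: Peri-Event Quantification of Receiver Startle Responses from
    Pose-Tracking Keypoints
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantifies startle responses of signal receivers during
    courtship from 2-D pose-estimation keypoint tracks.  Computes a
    body-height-normalised relative displacement signal from beak-tip
    coordinates, baseline-corrected peri-event delta statistics around
    display-element onsets, individual-balanced bootstrap null
    distributions with empirical p-values, window- and baseline-size
    robustness sweeps, leave-one-out stability checks, and a
    courter-status contrast for bower-exit probability.  Ships a
    synthetic-data generator that emulates the statistical structure of
    field recordings (keypoint jitter, mis-detections, display-element
    streams, injected startle pulses) so that every pipeline stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
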