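Package: restdyn
Title: Predicting Dynamic Ranges of Prefrontal EEG Features from Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening users of passive brain-computer interfaces
    (pBCI) from short resting-state EEG. Implements a full analysis pipeline for
    two-channel prefrontal (Fp1/Fp2) recordings: preprocessing (downsampling,
    zero-phase band-pass filtering, sliding-window segmentation, eye-blink
    detection and rejection, LMS-based EOG adaptive filtering), quantitative EEG
    band-power features (frontal alpha asymmetry, relative theta and low-beta
    power), dynamic ranges measured as interquartile ranges of per-segment
    feature series, a 112-predictor resting-state feature bank, and regression
    models with forward sequential feature selection under
    leave-one-participant-out cross-validation scored by normalized RMSE and
    compared with paired permutation tests. A synthetic cohort generator with
    known ground truth makes every stage testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    kernlab,
    rpart,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
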