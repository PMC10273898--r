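Package: gazediff
Title: Group Differences in Gaze Behaviour to Dynamic Stimuli
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-wise analysis of eye-gaze recordings made while groups of
    participants watch dynamic (video) stimuli. Implements the
    distance-to-group-centre divergence statistic: per video frame, each
    participant's Euclidean distance to their own group's mean gaze position
    is compared between groups with a Student's t-test, and videos are
    summarised by the percentage of frames showing a nominally significant
    difference. Includes Gambling Craving Scale (GACS) scoring with a
    median-split grouping, ranking and selection of the most discriminative
    videos, leakage-safe repeated 80/20 holdout classification of group
    membership from average viewing positions, and a synthetic gaze-cohort
    generator for end-to-end validation and type-I-error calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    withr,
    class,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
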