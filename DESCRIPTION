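Package: motionscreen
Title: Camera-Based Assessment of Functional Movement Tests from 2D Pose Keypoints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the execution quality of clinical functional tests (the
    Single Leg Squat Test and the Step Down Test) from markerless motion
    capture. Reads per-frame 2D pose keypoints in the OpenPose BODY_25 JSON
    dialect, computes kinematic signals (joint angles, keypoint-pair
    orientations, trunk-normalized relative distances), reduces them to
    range-of-movement features, gates multi-rater binary expert assessments by
    Fleiss's kappa inter-rater agreement, and trains and evaluates a boosted
    decision-tree classifier that predicts the experts' error ratings. A
    synthetic skeleton-motion simulator with injectable execution errors and
    simulated raters provides ground truth for end-to-end validation without
    any recorded video data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
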