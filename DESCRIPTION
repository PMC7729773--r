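Package: posefall
Title: Two-Stage Fall Recognition from 2D Skeleton Keypoint Streams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognises falls in streams of 2D human-skeleton keypoints
    (OpenPose BODY_25 dialect). Per-frame posture features (segment
    deflection angles against the vertical and the spine-to-waist ratio)
    are integrated into tendency and steady symbols and a three-level
    human state (stable, fluctuating, disorder). A time-continuous
    detector tracks a reference template of the last stable pose, opens a
    non-stationary residence period after three consecutive unstable
    frames, and summarises it by a compare value (cumulative normalised
    centroid descent), an energy value (lower-limb vertical dispersion)
    and a state score, which a classifier (SVM, KNN, decision tree or
    random forest) labels as fall or activity of daily living. A seeded
    stick-figure motion generator produces labelled synthetic sequences
    for end-to-end testing without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    rpart,
    class,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
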