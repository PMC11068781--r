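Package: divekin
Title: Markerless Motion-Capture Kinematics of Goalkeeper Penalty Dives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-camera markerless motion capture of
    soccer goalkeeper penalty dives: 11-parameter DLT camera calibration and
    two-or-more-view 3D reconstruction of BODY_25 pose keypoints, zero-lag
    Butterworth smoothing with residual-analysis cutoff selection, segmental
    whole-body centre-of-mass estimation, dive-cycle event detection with
    0-100% time normalization, six kinematic outcome variables (peak
    resultant velocity, time to peak, knee angle curve, frontal step
    distance, preparatory stance width, frontal departure angle), and the
    matching statistics: 1D statistical parametric mapping with permutation
    inference on normalized curves, paired t tests, mixed two-way
    repeated-measures ANOVA with Bonferroni contrasts, and Cohen's d.
    Includes a synthetic dive generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
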