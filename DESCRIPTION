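Package: gaitpose
Title: Pose-Based Gait Analysis for Broilers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn per-frame 2D keypoint trajectories of broilers
    walking a corridor into leg pose features associated with walking ability.
    Reads DeepLabCut-dialect keypoint tables, detects double-support and
    maximum-leg-lift poses from foot trajectory extrema, computes seven
    geometric leg features (hock joint angle, shank-vs-floor angle, normalized
    tibiotarsus and shank lengths, hock-knee and hock-feet distance ratios,
    relative step height), summarises multi-rater gait scores (mean score,
    binary gait class, Fleiss' and Cohen's weighted kappa), and fits the
    class-difference statistics (2xIQR outlier screen, linear models with
    interaction dropping, Pearson correlations, and a generalized estimating
    equations body-weight contrast). A kinematic trajectory simulator with
    per-bird anatomy, gait-class effects, detection noise and likelihood
    dropout provides reproducible synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
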