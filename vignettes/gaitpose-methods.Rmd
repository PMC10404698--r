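---
title: "Pose-based gait analysis for broilers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pose-based gait analysis for broilers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitpose)
```

## The problem

Impaired walking ability is a major welfare and economic concern in broiler
production, and breeding against it needs objective, high-throughput
phenotypes. One promising route films individual birds from behind as they
walk a narrow corridor (3 m x 0.4 m, 12 fps, 1280 x 720 px), tracks eight
body keypoints (head, neck, and the knee, hock and foot of each leg) with a
pose-estimation network, and reduces the keypoint trajectories to a handful
of interpretable leg pose features. `gaitpose` implements that reduction —
gait-phase detection, pose-frame selection, feature geometry — together with
the scoring and statistical layer that relates the features to expert gait
scores, and a kinematic simulator that generates realistic synthetic
cohorts for development, testing and power exploration.

Coordinates follow image conventions throughout: the origin is top-left and
y grows downward, so "lower on the ground" always means larger y. Frames are
indexed from 0 and clip bounds are inclusive.

## From trajectories to poses

A `tracked_trial` holds per-frame (x, y, likelihood) series for the eight
parts plus metadata. Cleaning proceeds in fixed stages:

1. **Clip** to the manually recorded start/end of the walking test
   (`clip_trial()`).
2. **Trim** the first and last 10% of the clipped frames
   (`trim_edges()`); the recording edges show the bird being placed or
   mingling with birds resting at the far end. `floor(0.10 * n)` frames are
   dropped from each end — the rounding is symmetric by construction.
3. **Mask** frames whose six leg keypoints do not all reach the likelihood
   threshold (0.6, the usual network default); only such pose-eligible
   frames can become poses (`mask_low_likelihood()`). All six are required
   simultaneously because every feature needs several leg points measured
   in the same frame.
4. Optionally **smooth** each coordinate series with a cubic smoothing
   spline over eligible frames (`smooth_trajectories()`). The stage is off
   by default: the exact filter used by tracking software is generally
   unknown and the package's detection-noise defaults are calibrated
   against unfiltered keypoints. When enabled, a generalized
   cross-validated spline is fitted per series and its correction is capped
   at a multiple of the series' estimated frame-to-frame noise SD, so on
   noiseless input the stage is exactly an identity. The noise SD is
   estimated from the lower quartile of |successive differences| (divided
   by 0.4506, its expectation ratio for Gaussian noise): at least half the
   frames of any keypoint are quasi-stationary stance frames, so this
   quartile sits inside the pure-noise part of the distribution and is 0
   for noiseless input.

Two poses of interest are then detected from the feet's y-trajectories
(`find_foot_extrema()`, `extract_poses()`):

* **Double support** — both feet on the ground. Ground contacts are local
  y-maxima, leg lifts local y-minima, with a minimum prominence of 3
  estimated noise SDs so detector jitter cannot pass for a step. Candidate
  frames have both feet within a contact band (default 10% of the
  normalization factor) around *their own* contact level (the median y at
  that foot's contact extrema). Up to 3 frames are selected to minimize the
  vertical difference between the feet; the implementation minimizes
  `|(yL - contactL) - (yR - contactR)|`, i.e. each foot's deviation from
  its own ground level. On level ground this is identical to the raw
  left-right difference; on uneven litter it prevents frames in which the
  higher-placed foot has just lifted from faking a level stance.
* **Maximum leg lift** — for each side, candidate frames are lift minima of
  that foot while the other foot is in contact; up to 3 frames are selected
  to maximize the vertical difference between the feet.

Selected frames of one kind must be at least `min_separation` frames apart
(default 6, half the typical stride period at 12 fps) so they come from
distinct gait cycles. Selection is solved exactly by a small dynamic
programme (maximize the number selected, then optimize the total
objective); ties resolve to earlier frames, making extraction fully
deterministic. A bird with no pose of any kind (e.g. one that sits through
the test, whose leg keypoints are occluded and low-likelihood) raises a
`no-walk` error and is excluded and logged, mirroring how non-walkers must
be excluded from analyses.

## The seven features

All features are computed per selected frame and averaged over the (up to
3) frames of the relevant pose kind (`aggregate_features()`).
`normalization_factor()` is the vertical distance from the highest knee to
the lowest foot of the same frame, recomputed per frame; dividing by it
makes lengths and step height invariant to how far the bird is from the
camera.

At double support:

* `hock_joint_angle` (degrees, per side): interior angle at the hock
  between the hock-knee and hock-foot segments, via the arc-cosine of the
  normalized dot product. The interior angle (not its reflex) is used: a
  straight leg gives 180 degrees and reported magnitudes near 150-156
  degrees are only consistent with the interior reading. Crouching gives
  sharper angles.
* `shank_floor_angle` (degrees, per side): angle between the foot-to-hock
  segment and the horizontal ray from that foot toward the body midline,
  taken as the mean x of the two feet in the same frame — self-contained
  per frame and robust to lateral sway. Vertical shank = 90; hock medial
  of the foot < 90.
* `tibiotarsus_rel_length`, `shank_rel_length` (unitless, per side):
  knee-hock and hock-foot segment lengths over the normalization factor.
* `hock_knee_ratio`, `hock_feet_ratio` (unitless, no sides): horizontal
  hock spacing over horizontal knee (respectively feet) spacing. A low
  hock-feet ratio means feet splayed relative to the hocks.

At maximum leg lift:

* `step_height_rel` (%): grounded-foot y minus lifted-foot y, over the
  same frame's normalization factor; left steps yield side `left`, right
  steps side `right`. A negative value flags a mis-selected candidate and
  is returned with a warning rather than silently dropped.

All features are invariant to translation, scaling and left-right
mirroring (mirroring swaps sides); the test suite asserts these properties
on simulated poses. Sides are kept separate until the statistics stage,
which models side explicitly.

## Gait scoring and agreement

Gait is scored 0-5 by four raters on the final recording day; each bird
gets the mean score (`mean_gait_score()`) and a binary class: good (mean
at most 2) vs suboptimal (above 2) (`classify_gait()`; 2.5 and 3 are the
usual robustness cutoffs). Inter-rater agreement uses Fleiss' kappa over
the six categories; intra-rater reliability uses Cohen's weighted kappa on
a repeat-scored subset, with linear weights by default (the quadratic
scheme is available; reports name the scheme, and no numerical equivalence
to any specific software default is claimed). Verbal bands follow the
conventional ranges (0.21-0.40 fair, 0.41-0.60 moderate, ...), printed
endpoints upper-inclusive. Both statistics are implemented directly from
their defining formulas and are checked in the tests against independent
reference implementations on fixed tables.

## The statistical layer

* **Outlier screen** (`remove_outliers()`, `filter_outliers()`): within
  each age-by-feature combination, pooling sides, values outside
  `[Q1 - 2 IQR, Q3 + 2 IQR]` are dropped. Quartiles use linear
  interpolation (type 7; configurable). For Gaussian data these fences sit
  near ±3.4 SD, so clean data essentially never loses records (the removal
  rate is well under one per thousand, though with 164 records a single
  removal does occur in a nontrivial fraction of cohorts — the screen is a
  contamination guard, not a tail trimmer).
* **Class differences** (`feature_class_model()`, `ratio_class_model()`):
  ordinary least squares on side-level records of one feature at the
  analysis age, `value ~ class + body weight + side + class:side`; if the
  class-by-side interaction is not significant at 0.05 it is removed and
  the model refitted. The reported difference (suboptimal minus good) is
  the side-averaged marginal class effect: identical to the class
  coefficient after the interaction is dropped, and equal to the class
  coefficient plus half the interaction coefficient when it is retained —
  the marginal effect is the estimand comparable across models and far
  more stable than a single-side coefficient conditioned on a significant
  interaction. The two distance ratios have no sides and use
  `value ~ class + body weight`. The "value at good gait" is the
  model-implied good-class mean at the mean body weight, averaged over
  sides; the percentage difference is `100 * diff / value_at_good` with a
  CI obtained by scaling the class-coefficient CI by the same baseline
  (a delta-method treatment holding the baseline fixed). No
  multiple-testing correction is applied, and reports say so.
* **Correlations** (`feature_correlations()`): Pearson correlations across
  birds (sides averaged within bird first) at the analysis age, two-sided
  P from the t transform.
* **Body weight** (`bodyweight_class_contrast()`): weights are repeated
  within bird over ages, so the class contrast per age comes from a
  Gaussian marginal model — generalized estimating equations with an
  exchangeable working correlation on bird and robust (sandwich) standard
  errors, implemented directly (iterated generalized least squares with a
  moment estimator for the working correlation). In the independence limit
  it reproduces OLS exactly, and on a fixed panel it matches an
  independent GEE implementation to six decimals (see the tests).
* `significance_label()`: P at most 0.05 significant; 0.05 < P at most
  0.10 a tendency.

## The synthetic cohort generator

No public recordings exist for this kind of corridor test, so
`simulate_cohort()` stands in for the videos. It is a first-class, tested
component, not a fixture: it draws per-bird anatomy, builds per-age
double-support leg geometry, synthesizes rear-view keypoint trajectories,
and emits body weights and four-rater scores.

**Kinematics.** Feet alternate stance (constant ground level) and swing (a
half-sine lift); the stride period is 1 s at 12 fps and the stance fraction
0.6, so double support exists twice per stride and an 8 s trial offers at
least 3 widely separated candidates per pose kind. The swing occupies an
odd number of frames so its apex falls exactly on a sampled frame, and the
swing amplitude is scaled so the extracted relative step height equals the
bird's ground truth exactly. Hocks rise with half the foot lift; knees stay
at their double-support height, so the per-frame normalization factor is
preserved through the stride. The whole body sways laterally (a few px at
stride frequency), which no feature sees (all are translation invariant).
A camera-distance scale drift (birds shrinking as they walk away) exists as
an option and is off by default.

**Geometry.** Each leg is constructed from its drawn hock angle, shank
angle and relative tibiotarsus length, scaled to the leg's vertical extent;
the foot spread realizes the bird's target hock-feet ratio. Ground truth
for all seven features is obtained by running the package's own feature
functions on the constructed noiseless pose, which makes the
generator-feature inverse consistency exact by construction: the test suite
asserts agreement to 1e-6 relative error in the noiseless limit, and the
observed error is at machine precision.

**Population structure.** A per-leg latent "crouch" factor — partly loaded
on the bird's body-weight deviation (heavier birds stand more crouched) —
couples the hock and shank angles and, through an effective slope, the
hock-feet ratio, reproducing the strong observed correlations among these
features. Relative segment lengths are drawn per leg with a between-bird
share; step heights load negatively on body weight. Two small but
load-bearing asymmetries are modelled: the two legs' vertical extents
differ by a few percent (pelvis and stance are never perfectly level), and
the two feet rest at slightly different litter heights (wood-shavings
bedding is not flat). These matter because the normalization factor mixes
legs (lowest foot to highest knee): with a rigid, level-ground geometry the
identity `sin(shank angle) * shank_rel + sin(hock - shank) * tibio_rel = 1`
would force the two relative lengths into a correlation near -1, whereas
the reported value is near -0.58; litter and extent variability, plus the
keypoint error structure, reproduce the observed regime.

**Detection error.** Every coordinate gets white Gaussian noise (default
4 px, the scale of a typical keypoint-model test error). Knees are special:
they sit under a thick feather layer and are the hardest points to place,
so their frame-level jitter is inflated (x1.2) and, more importantly, each
knee carries a bird-specific systematic placement offset (SD 3 px) that
persists across the frames of a recording. Per-frame likelihoods fall below
the 0.6 threshold with the dropout probability (default 0.05 per leg
keypoint; higher for head/neck), and non-walking birds have all leg
likelihoods below threshold, so they fail pose extraction exactly as
sitting birds do in practice.

**Calibration.** The population parameters are stated as good-gait-class
means with additive suboptimal-class effects (hock angle -2.2 degrees,
shank angle -1.3, relative tibiotarsus +0.01, hock-feet ratio -0.03, step
height -4.5 points; body weight +9.7/+26.4/+64.3 g at 14/21/33 d). Because
extraction through noisy keypoints both spreads and slightly biases the
measured features, the default means and between-bird SDs are calibrated by
a fixed-point iteration so that the *pipeline-measured* cohort statistics —
not the latent draws — reproduce the descriptive statistics of the study
conditions (e.g. at 33 d: hock angle 151.9 +- 6.9 degrees, shank-floor
angle 82.4 +- 5.8, relative tibiotarsus 0.55 +- 0.05, step height
35.9 +- 9.6%, hock-feet ratio 0.85). The hock-knee ratio is emergent from
the constructed geometry rather than drawn (a pose cannot realize seven
features independently); its simulated mean (~0.66 at 33 d) sits close to
the observed 0.65. The class effects themselves are *not* adjusted: the
small attenuations the measurement process induces (hock difference
recovered as about -2.3 on average, step height as about -4.0) are honest
properties of the pipeline.

**Raters.** Each bird has a latent lameness value by class; each rater
rounds latent-plus-bias-plus-noise to the 0-5 scale. Scores are redrawn (up
to 100 times, with a deterministic fallback) until good birds have mean at
most 2 and suboptimal birds above 2, so the score-derived classes match the
generating classes. Rater noise (SD 0.40) and the rater-bird repeatability
correlation (0.93) are set so that four-rater Fleiss' kappa lands in the
fair band (~0.27-0.30) while each rater's own repeat-scoring weighted kappa
stays in the good-excellent range (at least 0.67), matching the agreement
regime such scoring studies report.

**What the generator does not emulate.** Real rear-view video adds
perspective scale drift (off by default here), occlusions between birds,
identity switches, non-stationary gait (speeding up, stopping), and
correlated, non-Gaussian keypoint failures. Passing recovery tests on these
synthetic cohorts therefore demonstrates that the pipeline's rules and
statistics are implemented correctly and are consistent with the study
conditions — not that the pipeline would achieve the same accuracy on
arbitrary new video.

## Numerical choices and degenerate inputs

* Quartiles: type 7 (linear interpolation), configurable.
* Extremum detection collapses plateaus to their middle frame; series
  edges are never extrema; constant series have none.
* Selection ties resolve to earlier frames; the dynamic programme is exact
  for the small k in use (checked against exhaustive enumeration).
* Degenerate poses (non-positive normalization factor, zero-length
  segments, feet coincident in x, knees coincident in x) raise descriptive
  errors rather than returning NaN.
* A frame is eligible only if all six leg likelihoods are at least the
  threshold; the boundary is inclusive.
* With fewer than 4 values the outlier screen does nothing (warning);
  with fewer than 4 eligible frames a series is left unsmoothed (warning).
* All simulation randomness flows from the seed passed to
  `simulate_cohort()`; trial-level seeds are drawn from it, and identical
  (parameters, bird, seed) triples give bit-identical trials.

## Problem sizes

The default study conditions are 84 birds (48 good, 36 suboptimal) per
cohort at up to three ages, 8 s trials at 12 fps (96 frames). A full
single-age cohort — simulation, cleaning, extraction, features and the
complete statistical layer — runs in roughly two seconds, which is what
makes the replication studies in the test suite (100 simulated cohorts for
the class-effect recovery, 200 null fits for the type-I error check)
practical as ordinary tests.

## Known limitations

* The spline stage does not claim equivalence to any specific tracker's
  filter; its parameters are exposed instead.
* Whether features should be computed from raw or smoothed coordinates is
  a config choice; the defaults use raw coordinates.
* The marginal-model contrast assumes an exchangeable working correlation;
  robust errors protect the inference, not the efficiency, if that is
  misspecified.
* Percentage-difference CIs hold the baseline fixed (delta method on the
  class coefficient only).
* The generator's calibration targets the descriptive statistics of one
  set of corridor-test conditions; other flocks, ages or camera setups
  would need recalibration.
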