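#' Trajectory cleaning configuration
#'
#' Settings for the trajectory-cleaning stage: the fraction of frames dropped
#' at each end of a clipped trial, the keypoint likelihood threshold below
#' which a detection is not trusted, and the optional spline smoothing of the
#' coordinate series.
#'
#' @param trim_fraction Fraction of frames discarded at the start and again at
#'   the end of the clipped trial (default 0.10). Must lie in \[0, 0.5).
#' @param likelihood_threshold Minimum detection confidence for a keypoint to
#'   count as reliable (default 0.6, the DeepLabCut default). In (0, 1).
#' @param smoothing Either `"none"` (default: feed the extractor the raw
#'   detections, whose noise level the downstream defaults are calibrated
#'   for) or `"spline"` (cubic smoothing spline per coordinate series over
#'   eligible frames).
#' @param smoothing_cap_sd Cap on how far smoothing may move any point,
#'   expressed as a multiple of the estimated frame-to-frame noise SD of the
#'   series; with noiseless input the estimate is 0 and smoothing is an
#'   identity.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(trim_fraction = 0.10,
                            likelihood_threshold = 0.6,
                            smoothing = c("none", "spline"),
                            smoothing_cap_sd = 4) {
  smoothing <- match.arg(smoothing)
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop("trim_fraction must lie in [0, 0.5)")
  if (likelihood_threshold <= 0 || likelihood_threshold >= 1)
    stop("likelihood_threshold must lie in (0, 1)")
  if (smoothing_cap_sd <= 0) stop("smoothing_cap_sd must be positive")
  structure(list(trim_fraction = trim_fraction,
                 likelihood_threshold = likelihood_threshold,
                 smoothing = smoothing,
                 smoothing_cap_sd = smoothing_cap_sd),
            class = "cleaning_config")
}

#' Discard the first and last fraction of a walking trial
#'
#' Removes `floor(trim_fraction * n)` frames from each end of the clipped
#' trial (n being the clipped length). The head of a recording typically shows
#' the bird being placed in the corridor, and near the end the bird of
#' interest mixes with birds resting at the far end, so both edges are
#' unreliable for pose extraction.
#'
#' @param trial A clipped [tracked_trial()].
#' @param config A [cleaning_config()].
#' @return The trimmed `tracked_trial`.
#' @export
trim_edges <- function(trial, config = cleaning_config()) {
  validate_trial(trial)
  n <- n_frames(trial)
  if (n < 10) stop("trial too short to trim: ", n, " frames")
  k <- floor(config$trim_fraction * n)
  if (k == 0) return(trial)
  keep <- (k + 1):(n - k)
  trial <- subset_frames(trial, keep)
  trial$start_frame <- min(trial$frames)
  trial$end_frame <- max(trial$frames)
  trial
}

#' Mark pose-eligible frames by leg-keypoint likelihood
#'
#' A frame is eligible for pose extraction only if all six leg keypoints
#' (both knees, hocks and feet) reach the likelihood threshold simultaneously;
#' every feature needs several leg points in the same frame, so a single
#' unreliable leg detection spoils the frame. Head and neck confidences do not
#' affect eligibility and no coordinate is altered.
#'
#' @param trial A [tracked_trial()].
#' @param config A [cleaning_config()].
#' @return The trial with an `eligible` logical mask attached.
#' @export
mask_low_likelihood <- function(trial, config = cleaning_config()) {
  validate_trial(trial)
  lik <- trial$likelihood[, leg_parts(), drop = FALSE]
  trial$eligible <- as.logical(apply(lik >= config$likelihood_threshold, 1, all))
  if (n_frames(trial) == 0) trial$eligible <- logical(0)
  trial
}

# Robust frame-to-frame noise SD of a series. Uses the lower quartile of
# |diff|: during walking at least half the frames of any keypoint are
# quasi-stationary (stance), so the lower quartile sits inside the pure-noise
# part of the diff distribution and is exactly 0 for noiseless input. For
# iid Gaussian noise, |diff| ~ |N(0, sd*sqrt(2))| whose lower quartile is
# qnorm(0.625) * sqrt(2) * sd = 0.4506 * sd.
estimate_noise_sd <- function(v) {
  d <- abs(diff(v))
  d <- d[is.finite(d)]
  if (length(d) < 3) return(0)
  unname(stats::quantile(d, 0.25, names = FALSE) / 0.4506)
}

#' Smooth keypoint trajectories
#'
#' Fits a cubic smoothing spline (generalized cross-validated) to each
#' coordinate series over the eligible frames only, leaving likelihoods and
#' ineligible frames untouched. The fitted value is clamped so that no point
#' moves further than `smoothing_cap_sd` times the series' estimated noise SD;
#' on noiseless input the cap is 0 and the stage is an identity. Series with
#' fewer than 4 eligible frames are left unsmoothed with a warning.
#'
#' @param trial A [tracked_trial()] with an eligibility mask (see
#'   [mask_low_likelihood()]).
#' @param config A [cleaning_config()]; `smoothing = "none"` is an identity.
#' @return The smoothed `tracked_trial`.
#' @export
smooth_trajectories <- function(trial, config = cleaning_config()) {
  validate_trial(trial)
  if (config$smoothing == "none") return(trial)
  if (is.null(trial$eligible))
    trial <- mask_low_likelihood(trial, config)
  el <- which(trial$eligible)
  for (part in body_parts()) {
    ok <- el[is.finite(trial$x[el, part]) & is.finite(trial$y[el, part])]
    if (length(ok) < 4) {
      if (length(el) > 0)
        warning("part ", part, " has fewer than 4 eligible frames; left unsmoothed")
      next
    }
    for (axis in c("x", "y")) {
      v <- trial[[axis]][ok, part]
      cap <- config$smoothing_cap_sd * estimate_noise_sd(v)
      if (cap == 0 || stats::var(v) == 0) next
      fit <- try(stats::smooth.spline(ok, v, cv = FALSE, keep.data = FALSE),
                 silent = TRUE)
      if (inherits(fit, "try-error")) next
      sm <- stats::predict(fit, ok)$y
      sm <- pmin(pmax(sm, v - cap), v + cap)
      trial[[axis]][ok, part] <- sm
    }
  }
  trial
}

#' Likelihood summary by age and body part
#'
#' Percentage of frames whose keypoint likelihood reaches the threshold, per
#' body part, averaged over birds within each age: the standard check of how
#' confidently the pose model located each part across the recordings.
#'
#' @param trials A list of [tracked_trial()] objects.
#' @param config A [cleaning_config()] (supplies the threshold).
#' @return Data frame with columns `age_days`, `body_part`,
#'   `pct_above_threshold`.
#' @export
likelihood_summary <- function(trials, config = cleaning_config()) {
  if (length(trials) == 0) stop("at least one trial required")
  tau <- config$likelihood_threshold
  per <- do.call(rbind, lapply(trials, function(tr) {
    data.frame(age_days = tr$age_days,
               body_part = body_parts(),
               pct = 100 * colMeans(tr$likelihood[, body_parts(), drop = FALSE] >= tau),
               row.names = NULL)
  }))
  out <- stats::aggregate(pct ~ age_days + body_part, data = per, FUN = mean)
  names(out)[names(out) == "pct"] <- "pct_above_threshold"
  out[order(out$age_days, match(out$body_part, body_parts())), , drop = FALSE]
}
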