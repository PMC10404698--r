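#' Body part names
#'
#' The eight tracked body parts, in canonical column order: head, neck, then
#' knee, hock and foot for the left and right leg. The six leg keypoints
#' (knees, hocks, feet) are the ones used for pose extraction and features.
#'
#' @return Character vector of part names.
#' @export
body_parts <- function() {
  c("head", "neck",
    "knee_left", "knee_right",
    "hock_left", "hock_right",
    "foot_left", "foot_right")
}

#' @rdname body_parts
#' @export
leg_parts <- function() {
  c("knee_left", "knee_right", "hock_left", "hock_right",
    "foot_left", "foot_right")
}

#' Construct a tracked trial
#'
#' A `tracked_trial` holds the per-frame keypoint series of one bird walking
#' the corridor during one recording: for each of the eight body parts an
#' (x, y, likelihood) triple per frame, plus trial metadata. Coordinates use
#' image conventions (origin top-left, y increases downward, so "lower on the
#' ground" means larger y). Frames are indexed from 0 and clip bounds are
#' inclusive. Missing detections are stored as `NA` coordinates with
#' likelihood 0 so that all series stay frame-aligned.
#'
#' @param x,y,likelihood Numeric matrices, frames x 8 parts, with column names
#'   equal to [body_parts()]. Likelihoods must lie in \[0, 1\].
#' @param bird_id Character scalar identifying the bird.
#' @param age_days Positive integer age at recording.
#' @param fps Frame rate in frames per second (default 12).
#' @param frame_size Integer vector `c(width, height)` in pixels,
#'   default `c(1280, 720)`.
#' @param start_frame,end_frame Inclusive 0-based manual clip bounds of the
#'   walking trial, or `NA` if not set.
#' @return An object of class `tracked_trial`.
#' @export
tracked_trial <- function(x, y, likelihood, bird_id = "bird",
                          age_days = 33L, fps = 12,
                          frame_size = c(1280L, 720L),
                          start_frame = NA_integer_,
                          end_frame = NA_integer_) {
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  n <- nrow(x)
  for (m in list(x, y, likelihood)) {
    if (nrow(m) != n || ncol(m) != 8L)
      stop("x, y and likelihood must be frames x 8 matrices of equal size")
  }
  if (is.null(colnames(x))) colnames(x) <- body_parts()
  colnames(y) <- colnames(likelihood) <- colnames(x)
  if (!identical(sort(colnames(x)), sort(body_parts())))
    stop("unknown body-part columns; expected: ",
         paste(body_parts(), collapse = ", "))
  x <- x[, body_parts(), drop = FALSE]
  y <- y[, body_parts(), drop = FALSE]
  likelihood <- likelihood[, body_parts(), drop = FALSE]
  bad <- !is.na(likelihood) & (likelihood < 0 | likelihood > 1)
  if (any(bad)) stop("likelihood values must lie in [0, 1]")
  likelihood[is.na(likelihood)] <- 0
  likelihood[is.na(x) | is.na(y)] <- 0
  trial <- structure(list(
    bird_id = as.character(bird_id),
    age_days = as.integer(age_days),
    fps = fps,
    frame_size = as.integer(frame_size),
    frames = if (n > 0) 0:(n - 1L) else integer(0),
    x = x, y = y, likelihood = likelihood,
    start_frame = as.integer(start_frame),
    end_frame = as.integer(end_frame),
    eligible = NULL
  ), class = "tracked_trial")
  validate_trial(trial)
  trial
}

validate_trial <- function(trial) {
  stopifnot(inherits(trial, "tracked_trial"))
  n <- n_frames(trial)
  if (!is.na(trial$start_frame) && !is.na(trial$end_frame)) {
    if (trial$start_frame < 0 || trial$end_frame < trial$start_frame ||
        trial$end_frame > max(trial$frames, -1L))
      stop("clip bounds must satisfy 0 <= start_frame <= end_frame < n_frames")
  }
  if (!is.null(trial$eligible) && length(trial$eligible) != n)
    stop("eligibility mask length must match the number of frames")
  invisible(trial)
}

#' Number of frames in a trial
#' @param trial A [tracked_trial()].
#' @return Integer frame count.
#' @export
n_frames <- function(trial) nrow(trial$x)

#' @export
print.tracked_trial <- function(x, ...) {
  cat(sprintf("<tracked_trial> bird %s, age %d d, %d frames @ %g fps\n",
              x$bird_id, x$age_days, n_frames(x), x$fps))
  cat(sprintf("  frame size %d x %d px; clip bounds [%s, %s]\n",
              x$frame_size[1], x$frame_size[2],
              ifelse(is.na(x$start_frame), "unset", x$start_frame),
              ifelse(is.na(x$end_frame), "unset", x$end_frame)))
  if (!is.null(x$eligible))
    cat(sprintf("  %d/%d frames pose-eligible\n", sum(x$eligible), n_frames(x)))
  invisible(x)
}

subset_frames <- function(trial, idx) {
  trial$x <- trial$x[idx, , drop = FALSE]
  trial$y <- trial$y[idx, , drop = FALSE]
  trial$likelihood <- trial$likelihood[idx, , drop = FALSE]
  trial$frames <- trial$frames[idx]
  if (!is.null(trial$eligible)) trial$eligible <- trial$eligible[idx]
  trial
}

#' Clip a trial to its manual bounds
#'
#' Restricts the trial to the manually recorded start/end of the walking
#' test (inclusive on both ends); only frames inside this window are used
#' further. Metadata is preserved and the operation is idempotent.
#'
#' @param trial A [tracked_trial()] with `start_frame`/`end_frame` set.
#' @return The clipped `tracked_trial`.
#' @export
clip_trial <- function(trial) {
  validate_trial(trial)
  if (is.na(trial$start_frame) || is.na(trial$end_frame))
    stop("clip bounds unset: set start_frame and end_frame before clipping")
  keep <- trial$frames >= trial$start_frame & trial$frames <= trial$end_frame
  trial <- subset_frames(trial, keep)
  trial$start_frame <- min(trial$frames)
  trial$end_frame <- max(trial$frames)
  trial
}

#' Keypoint pixel error
#'
#' Euclidean distance, in pixels, between matched predicted and annotated
#' keypoints, and their mean: the standard accuracy metric for a pose
#' estimation model. Pairs can optionally be restricted to predictions whose
#' likelihood reaches a threshold before averaging.
#'
#' @param predicted,annotated Two-column (x, y) matrices of matched keypoints.
#' @param likelihood Optional numeric vector of prediction confidences.
#' @param threshold Optional likelihood threshold; pairs below it are dropped.
#' @return List with `per_keypoint` distances (px) and their `mean` (px).
#' @export
pixel_error <- function(predicted, annotated, likelihood = NULL,
                        threshold = NULL) {
  predicted <- as.matrix(predicted); annotated <- as.matrix(annotated)
  if (nrow(predicted) != nrow(annotated) || ncol(predicted) != 2 ||
      ncol(annotated) != 2)
    stop("predicted and annotated must be matched two-column (x, y) matrices")
  keep <- rep(TRUE, nrow(predicted))
  if (!is.null(threshold)) {
    if (is.null(likelihood)) stop("threshold given without likelihoods")
    keep <- likelihood >= threshold
  }
  d <- sqrt(rowSums((predicted - annotated)^2))[keep]
  if (length(d) == 0) stop("no keypoint pairs to average over")
  list(per_keypoint = d, mean = mean(d))
}
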