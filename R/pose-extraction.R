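#' Pose extraction configuration
#'
#' Settings for gait-phase detection and pose-frame selection.
#'
#' @param k Maximum number of frames selected per pose kind (default 3).
#' @param min_separation Minimum spacing, in frames, between two selected
#'   frames of the same pose kind (default 6, half the default stride period
#'   at 12 fps), so that the selected frames come from distinct gait cycles.
#' @param prominence_sd Minimum prominence of a foot-trajectory extremum,
#'   expressed as a multiple of the series' estimated frame-to-frame noise SD
#'   (default 3); keeps noise wiggles from counting as steps.
#' @param contact_tolerance Half-width of the ground-contact band around each
#'   foot's own contact level, as a fraction of the trial's typical
#'   normalization factor (default 0.10).
#' @return A list of class `pose_config`.
#' @export
pose_config <- function(k = 3L, min_separation = 6L, prominence_sd = 3,
                        contact_tolerance = 0.10) {
  if (k < 1) stop("k must be at least 1")
  if (min_separation < 1) stop("min_separation must be at least 1")
  if (prominence_sd < 0) stop("prominence_sd must be non-negative")
  if (contact_tolerance <= 0 || contact_tolerance >= 1)
    stop("contact_tolerance must lie in (0, 1)")
  structure(list(k = as.integer(k), min_separation = as.integer(min_separation),
                 prominence_sd = prominence_sd,
                 contact_tolerance = contact_tolerance),
            class = "pose_config")
}

# Local maxima of a numeric vector with plateau handling and prominence.
# Returns positions (indices into v). A plateau counts as one maximum at its
# middle; series edges are never maxima.
local_maxima <- function(v, min_prominence = 0) {
  n <- length(v)
  if (n < 3) return(integer(0))
  r <- rle(v)
  m <- length(r$values)
  if (m < 3) return(integer(0))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  is_peak <- c(FALSE, r$values[2:(m - 1)] > r$values[1:(m - 2)] &
                 r$values[2:(m - 1)] > r$values[3:m], FALSE)
  peaks <- which(is_peak)
  if (length(peaks) == 0) return(integer(0))
  idx <- (starts[peaks] + ends[peaks]) %/% 2L
  if (min_prominence > 0) {
    prom <- vapply(peaks, function(p) {
      h <- r$values[p]
      left <- r$values[1:(p - 1)]
      right <- r$values[(p + 1):m]
      hi_l <- which(left >= h)
      base_l <- if (length(hi_l) == 0) min(left) else
        min(left[max(hi_l):length(left)])
      hi_r <- which(right >= h)
      base_r <- if (length(hi_r) == 0) min(right) else min(right[1:min(hi_r)])
      h - max(base_l, base_r)
    }, 0)
    idx <- idx[prom >= min_prominence]
  }
  idx
}

local_minima <- function(v, min_prominence = 0) local_maxima(-v, min_prominence)

# Robust per-trial normalization-factor estimate: median over eligible frames
# of (lowest foot y - highest knee y).
estimate_norm_factor <- function(trial) {
  el <- which(trial$eligible)
  if (length(el) == 0) return(NA_real_)
  feet <- pmax(trial$y[el, "foot_left"], trial$y[el, "foot_right"])
  knees <- pmin(trial$y[el, "knee_left"], trial$y[el, "knee_right"])
  stats::median(feet - knees, na.rm = TRUE)
}

#' Find foot-trajectory extrema
#'
#' Detects the gait-cycle landmarks of each foot from its vertical (y)
#' trajectory over pose-eligible frames: ground contacts are local y-maxima
#' (image y grows downward) and leg lifts are local y-minima, subject to a
#' minimum prominence. Also estimates each foot's contact level (the y of the
#' ground under that foot) as the median y at its contact frames.
#'
#' @param trial A cleaned [tracked_trial()] with eligibility mask.
#' @param config A [pose_config()].
#' @return A list with per-foot components `left` and `right`, each holding
#'   `contacts` and `lifts` (frame numbers) and `contact_level` (px), plus the
#'   trial-level `norm_factor` estimate.
#' @export
find_foot_extrema <- function(trial, config = pose_config()) {
  if (is.null(trial$eligible)) stop("run mask_low_likelihood() first")
  el <- which(trial$eligible)
  if (length(el) == 0)
    stop("no-walk: no pose-eligible frames in trial of bird ", trial$bird_id)
  out <- list()
  for (side in c("left", "right")) {
    part <- paste0("foot_", side)
    yv <- trial$y[el, part]
    prom <- config$prominence_sd * estimate_noise_sd(yv)
    contacts <- el[local_maxima(yv, prom)]
    lifts <- el[local_minima(yv, prom)]
    contact_level <- if (length(contacts) > 0) {
      stats::median(trial$y[contacts, part])
    } else {
      # feet rest on the ground most of the time, so the upper half of the
      # y distribution sits at the contact level
      stats::median(yv[yv >= stats::median(yv)])
    }
    out[[side]] <- list(contacts = trial$frames[contacts],
                        lifts = trial$frames[lifts],
                        contact_level = contact_level)
  }
  out$norm_factor <- estimate_norm_factor(trial)
  out
}

# Exact small-k subset selection: among candidate frames (sorted) with values
# w, choose up to k frames, pairwise >= sep apart, maximizing the number
# selected and then the total of `w` (set minimize = TRUE to minimize).
# Dynamic programme over candidates; ties resolve to earlier frames.
select_frames_dp <- function(frames, w, k, sep, minimize = FALSE) {
  m <- length(frames)
  if (m == 0) return(integer(0))
  ord <- order(frames)
  frames <- frames[ord]; w <- w[ord]
  sign <- if (minimize) -1 else 1
  best <- matrix(-Inf, m, k)      # best signed sum with candidate i chosen last, j chosen
  parent <- matrix(0L, m, k)
  for (i in seq_len(m)) {
    best[i, 1] <- sign * w[i]
    for (j in 2:max(2, k)) {
      if (j > k) break
      prev <- which(frames <= frames[i] - sep)
      if (length(prev) == 0) next
      vals <- best[prev, j - 1]
      if (all(!is.finite(vals))) next
      b <- which.max(vals)        # earliest among ties (which.max picks first)
      if (is.finite(vals[b])) {
        best[i, j] <- vals[b] + sign * w[i]
        parent[i, j] <- prev[b]
      }
    }
  }
  jbest <- max(c(0L, which(apply(best, 2, function(col) any(is.finite(col))))))
  if (jbest == 0L) return(integer(0))
  i <- which.max(best[, jbest])
  sel <- integer(jbest); j <- jbest
  while (j >= 1) {
    sel[j] <- i
    i <- parent[i, j]
    j <- j - 1L
  }
  frames[sel]
}

pose_from_frame <- function(trial, frame, kind) {
  row <- match(frame, trial$frames)
  coords <- cbind(x = trial$x[row, leg_parts()],
                  y = trial$y[row, leg_parts()])
  rownames(coords) <- leg_parts()
  structure(list(frame = frame, kind = kind, coords = coords),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> %s @ frame %d\n", x$kind, x$frame))
  print(round(x$coords, 1))
  invisible(x)
}

# A foot is "at contact" in a frame when its y sits within the contact band
# around the foot's own contact level.
contact_ok <- function(trial, extrema, side, tol) {
  part <- paste0("foot_", side)
  abs(trial$y[, part] - extrema[[side]]$contact_level) <= tol
}

#' Select double-support poses
#'
#' Candidate frames are pose-eligible frames in which both feet sit within
#' the contact tolerance of their own contact level. Among candidates, up to
#' `k` frames are selected to minimize the vertical difference between the
#' left and right feet — each foot referenced to its own contact level, so
#' that a foot just leaving the ground cannot fake a level stance on uneven
#' litter — subject to the pairwise minimum frame separation; ties resolve
#' to the earlier frame.
#'
#' @param trial A cleaned [tracked_trial()].
#' @param extrema Output of [find_foot_extrema()].
#' @param k Maximum number of poses (default from config).
#' @param config A [pose_config()].
#' @return List of `pose` objects of kind `double_support`.
#' @export
select_double_support <- function(trial, extrema, k = NULL,
                                  config = pose_config()) {
  if (is.null(k)) k <- config$k
  tol <- config$contact_tolerance * extrema$norm_factor
  cand <- trial$eligible &
    contact_ok(trial, extrema, "left", tol) &
    contact_ok(trial, extrema, "right", tol)
  cand <- which(cand)
  if (length(cand) == 0)
    stop("no-double-support: no frame with both feet on the ground (bird ",
         trial$bird_id, ")")
  dev_l <- trial$y[cand, "foot_left"] - extrema$left$contact_level
  dev_r <- trial$y[cand, "foot_right"] - extrema$right$contact_level
  dy <- abs(dev_l - dev_r)
  sel <- select_frames_dp(trial$frames[cand], dy, k, config$min_separation,
                          minimize = TRUE)
  lapply(sel, pose_from_frame, trial = trial, kind = "double_support")
}

#' Select maximum-leg-lift step poses
#'
#' Candidate frames are pose-eligible lift minima of the stepping foot at
#' which the other foot is on the ground. Up to `k` frames are selected to
#' maximize the vertical difference between the feet (grounded minus lifted),
#' subject to the pairwise minimum frame separation.
#'
#' @param trial A cleaned [tracked_trial()].
#' @param extrema Output of [find_foot_extrema()].
#' @param side `"left"` or `"right"`: the stepping (lifted) leg.
#' @param k Maximum number of poses.
#' @param config A [pose_config()].
#' @return List of `pose` objects of kind `step_left` or `step_right`.
#' @export
select_steps <- function(trial, extrema, side = c("left", "right"), k = NULL,
                         config = pose_config()) {
  side <- match.arg(side)
  if (is.null(k)) k <- config$k
  other <- setdiff(c("left", "right"), side)
  tol <- config$contact_tolerance * extrema$norm_factor
  lifts <- extrema[[side]]$lifts
  rows <- match(lifts, trial$frames)
  ok <- trial$eligible[rows] & contact_ok(trial, extrema, other, tol)[rows]
  lifts <- lifts[ok]; rows <- rows[ok]
  if (length(lifts) == 0)
    stop("no-step: no ", side, " maximum leg lift found (bird ",
         trial$bird_id, ")")
  dy <- trial$y[rows, paste0("foot_", other)] - trial$y[rows, paste0("foot_", side)]
  sel <- select_frames_dp(lifts, dy, k, config$min_separation, minimize = FALSE)
  lapply(sel, pose_from_frame, trial = trial, kind = paste0("step_", side))
}

#' Extract the pose set of a trial
#'
#' Runs extremum detection and the three pose selections (double support,
#' left step, right step) on a cleaned trial. A pose kind with no candidates
#' is recorded as missing; if no pose of any kind can be found the bird did
#' not walk and a `no-walk` error is raised so the bird can be excluded.
#'
#' @param trial A cleaned [tracked_trial()] (clipped, trimmed, masked and
#'   optionally smoothed).
#' @param k Maximum frames per pose kind.
#' @param config A [pose_config()].
#' @return An object of class `pose_set`: bird/age metadata, the list of
#'   poses, and any per-kind failure messages.
#' @export
extract_poses <- function(trial, k = NULL, config = pose_config()) {
  if (is.null(k)) k <- config$k
  extrema <- find_foot_extrema(trial, config)   # errors no-walk if nothing eligible
  poses <- list()
  failures <- character(0)
  grab <- function(expr, kind) {
    res <- tryCatch(expr, error = function(e) conditionMessage(e))
    if (is.character(res)) failures[[kind]] <<- res else poses <<- c(poses, res)
  }
  grab(select_double_support(trial, extrema, k, config), "double_support")
  grab(select_steps(trial, extrema, "left", k, config), "step_left")
  grab(select_steps(trial, extrema, "right", k, config), "step_right")
  if (length(poses) == 0)
    stop("no-walk: no pose of any kind found for bird ", trial$bird_id)
  structure(list(bird_id = trial$bird_id, age_days = trial$age_days,
                 poses = poses, failures = failures),
            class = "pose_set")
}

#' @export
as.data.frame.pose_set <- function(x, ...) {
  rows <- lapply(x$poses, function(po) {
    coords <- as.vector(t(po$coords))
    names(coords) <- paste0(rep(c("x_", "y_"), 6),
                            rep(rownames(po$coords), each = 2))
    cbind(data.frame(bird_id = x$bird_id, age_days = x$age_days,
                     kind = po$kind, frame = po$frame),
          as.data.frame(t(coords)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pose_set <- function(x, ...) {
  kinds <- vapply(x$poses, `[[`, "", "kind")
  cat(sprintf("<pose_set> bird %s, age %d d: %s\n", x$bird_id, x$age_days,
              paste(sprintf("%s x%d", names(table(kinds)), table(kinds)),
                    collapse = ", ")))
  if (length(x$failures))
    cat("  missing:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}
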