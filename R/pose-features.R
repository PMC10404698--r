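#' Pose feature names
#'
#' The seven leg pose features: six quantified at double support (hock joint
#' angle, shank-vs-floor angle, relative tibiotarsus and shank lengths, and
#' the hock-knee and hock-feet horizontal distance ratios) and one at maximum
#' leg lift (relative step height). The two distance ratios have no
#' left/right counterpart; the others are computed per side.
#'
#' @return Character vector of feature names.
#' @export
feature_names <- function() {
  c("hock_joint_angle", "shank_floor_angle", "tibiotarsus_rel_length",
    "shank_rel_length", "hock_knee_ratio", "hock_feet_ratio",
    "step_height_rel")
}

pose_xy <- function(pose, part) pose$coords[part, c("x", "y")]

check_kind <- function(pose, kinds) {
  if (!pose$kind %in% kinds)
    stop("pose of kind '", pose$kind, "' not valid here; expected ",
         paste(kinds, collapse = " or "))
}

#' Normalization factor of a pose frame
#'
#' The vertical pixel distance between the highest knee and the lowest foot
#' of the frame (y grows downward, so this is `max(foot y) - min(knee y)`).
#' It scales the length features and the step height, making them
#' camera-distance invariant. Recomputed per frame.
#'
#' @param pose A `pose`.
#' @return Normalization factor in px (positive).
#' @export
normalization_factor <- function(pose) {
  nf <- max(pose$coords[c("foot_left", "foot_right"), "y"]) -
    min(pose$coords[c("knee_left", "knee_right"), "y"])
  if (!is.finite(nf) || nf <= 0)
    stop("degenerate pose: normalization factor not positive")
  nf
}

#' Hock joint lateral angle
#'
#' Interior angle at the hock between the hock-to-knee and hock-to-foot
#' segments, in degrees, via the arc-cosine of their normalized dot product.
#' A fully stretched leg gives 180 degrees; a crouched leg gives a sharper
#' (smaller) angle.
#'
#' @param pose A double-support `pose`.
#' @param side `"left"` or `"right"`.
#' @return Angle in degrees, in (0, 180\].
#' @export
hock_joint_angle <- function(pose, side = c("left", "right")) {
  side <- match.arg(side)
  check_kind(pose, "double_support")
  hock <- pose_xy(pose, paste0("hock_", side))
  v1 <- pose_xy(pose, paste0("knee_", side)) - hock
  v2 <- pose_xy(pose, paste0("foot_", side)) - hock
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("degenerate pose: zero-length leg segment")
  acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Medial shank-vs-floor angle
#'
#' Angle, in degrees, between the foot-to-hock segment (the shank) and the
#' horizontal unit vector pointing from that foot toward the body midline
#' (taken as the mean x of the two feet in the same frame). A perfectly
#' vertical shank gives 90 degrees; a hock medial of the foot gives less
#' than 90.
#'
#' @inheritParams hock_joint_angle
#' @return Angle in degrees.
#' @export
shank_floor_angle <- function(pose, side = c("left", "right")) {
  side <- match.arg(side)
  check_kind(pose, "double_support")
  fx <- pose$coords[c("foot_left", "foot_right"), "x"]
  foot <- pose_xy(pose, paste0("foot_", side))
  mid <- mean(fx)
  if (fx[1] == fx[2]) stop("degenerate pose: feet coincide in x, midline undefined")
  u <- c(sign(mid - foot[1]), 0)
  if (u[1] == 0) stop("degenerate pose: foot on the midline")
  v <- pose_xy(pose, paste0("hock_", side)) - foot
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("degenerate pose: zero-length shank")
  acos(min(1, max(-1, sum(v * u) / nv))) * 180 / pi
}

#' Relative segment lengths
#'
#' Tibiotarsus (knee-hock) and shank (hock-foot) lengths of one leg divided
#' by the frame's normalization factor.
#'
#' @inheritParams hock_joint_angle
#' @return Named vector `c(tibiotarsus_rel, shank_rel)`.
#' @export
relative_segment_lengths <- function(pose, side = c("left", "right")) {
  side <- match.arg(side)
  check_kind(pose, "double_support")
  nf <- normalization_factor(pose)
  knee <- pose_xy(pose, paste0("knee_", side))
  hock <- pose_xy(pose, paste0("hock_", side))
  foot <- pose_xy(pose, paste0("foot_", side))
  c(tibiotarsus_rel = sqrt(sum((knee - hock)^2)) / nf,
    shank_rel = sqrt(sum((hock - foot)^2)) / nf)
}

x_spread <- function(pose, what) {
  unname(abs(diff(pose$coords[paste0(what, c("_left", "_right")), "x"])))
}

#' Hock-knee and hock-feet distance ratios
#'
#' Ratio of the horizontal (x) distance between the hocks to that between
#' the knees (`hock_knee_ratio`) or between the feet (`hock_feet_ratio`).
#' Neither has a left/right counterpart. A hock-feet ratio below 1 means the
#' feet are spread wider than the hocks.
#'
#' @param pose A double-support `pose`.
#' @return Unitless ratio.
#' @export
hock_knee_ratio <- function(pose) {
  check_kind(pose, "double_support")
  denom <- x_spread(pose, "knee")
  if (denom == 0) stop("degenerate pose: knees coincide in x")
  x_spread(pose, "hock") / denom
}

#' @rdname hock_knee_ratio
#' @export
hock_feet_ratio <- function(pose) {
  check_kind(pose, "double_support")
  denom <- x_spread(pose, "foot")
  if (denom == 0) stop("degenerate pose: feet coincide in x")
  x_spread(pose, "hock") / denom
}

#' Relative step height
#'
#' At a maximum-leg-lift frame: the vertical difference between the grounded
#' and the lifted foot, as a percentage of the same frame's normalization
#' factor. The lifted foot is the pose's step side. A negative value (lifted
#' foot below the grounded one) indicates a mis-selected candidate and is
#' returned with a warning.
#'
#' @param pose A `pose` of kind `step_left` or `step_right`.
#' @return Step height in percent.
#' @export
step_height <- function(pose) {
  check_kind(pose, c("step_left", "step_right"))
  side <- sub("step_", "", pose$kind)
  other <- setdiff(c("left", "right"), side)
  nf <- normalization_factor(pose)
  val <- 100 * (pose$coords[paste0("foot_", other), "y"] -
                  pose$coords[paste0("foot_", side), "y"]) / nf
  if (val < 0)
    warning("negative step height at frame ", pose$frame,
            ": lifted foot below grounded foot")
  unname(val)
}

#' All features of one pose frame
#'
#' Computes every feature defined for the pose's kind: the six double-support
#' features (per side where applicable) or the step height.
#'
#' @param pose A `pose`.
#' @return Data frame with columns `feature`, `side`, `value`, `frame`.
#' @export
pose_features <- function(pose) {
  if (pose$kind == "double_support") {
    rows <- list()
    for (side in c("left", "right")) {
      rel <- relative_segment_lengths(pose, side)
      rows[[side]] <- data.frame(
        feature = c("hock_joint_angle", "shank_floor_angle",
                    "tibiotarsus_rel_length", "shank_rel_length"),
        side = side,
        value = c(hock_joint_angle(pose, side), shank_floor_angle(pose, side),
                  rel[["tibiotarsus_rel"]], rel[["shank_rel"]]))
    }
    rows$ratios <- data.frame(
      feature = c("hock_knee_ratio", "hock_feet_ratio"),
      side = "none",
      value = c(hock_knee_ratio(pose), hock_feet_ratio(pose)))
    out <- do.call(rbind, rows)
  } else {
    out <- data.frame(feature = "step_height_rel",
                      side = sub("step_", "", pose$kind),
                      value = step_height(pose))
  }
  out$frame <- pose$frame
  rownames(out) <- NULL
  out
}

#' Aggregate features over the selected frames
#'
#' Per feature and side, the arithmetic mean over the (up to 3) selected
#' frames of the relevant pose kind represents the bird's feature at that
#' age. Step heights from left steps get side `left`, from right steps side
#' `right`. Missing pose kinds yield absent records, not zeros.
#'
#' @param poseset A `pose_set` from [extract_poses()].
#' @return Data frame with columns `bird_id`, `age_days`, `feature`, `side`,
#'   `value`, `n_frames`.
#' @export
aggregate_features <- function(poseset) {
  stopifnot(inherits(poseset, "pose_set"))
  per_frame <- do.call(rbind, lapply(poseset$poses, pose_features))
  agg <- stats::aggregate(value ~ feature + side, data = per_frame, FUN = mean)
  n <- stats::aggregate(value ~ feature + side, data = per_frame, FUN = length)
  agg$n_frames <- n$value
  data.frame(bird_id = poseset$bird_id, age_days = poseset$age_days,
             agg[order(match(agg$feature, feature_names()), agg$side), ],
             row.names = NULL)
}
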