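#' Gait simulation parameters
#'
#' Population parameters of the kinematic walking simulator for one age.
#' Defaults describe rear-view recordings of male broilers walking a
#' 3 m x 0.4 m corridor at 12 fps, 1280 x 720 px. Anatomy means are
#' good-gait-class means; `class_effects` holds the additive shifts applied
#' to suboptimal-class birds. A per-leg latent "crouch" factor couples the
#' hock and shank angles (and the hock-feet distance ratio), partly loaded on
#' the bird's body-weight deviation, so that heavier birds stand more
#' crouched.
#'
#' @param age_days Age (14, 21 or 33 have calibrated defaults; other ages
#'   interpolate the nearest calibrated age).
#' @param noise_sd_px SD of the Gaussian pixel noise added to every
#'   coordinate (default 4 px, the scale of a typical keypoint-model test
#'   error).
#' @param dropout_prob Per-frame probability that a leg keypoint's
#'   likelihood falls below the threshold.
#' @param ... Named overrides of any default field.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(age_days = 33, noise_sd_px = 4, dropout_prob = 0.05,
                        ...) {
  ages <- c(14, 21, 33)
  a <- ages[which.min(abs(ages - age_days))]
  i <- match(a, ages)
  pick <- function(v) v[i]
  p <- list(
    age_days = as.integer(age_days),
    fps = 12,
    frame_size = c(1280L, 720L),
    trial_s = 8,
    stride_period_s = 1.0,
    stance_fraction = 0.6,
    ground_y = 620,
    lateral_sway_px = 3,
    scale_drift_per_s = 0,
    noise_sd_px = noise_sd_px,
    knee_noise_mult = 1.2,
    knee_bias_sd_px = 3,
    dropout_prob = dropout_prob,
    dropout_prob_headneck = 0.15,
    likelihood_threshold = 0.6,
    # good-class anatomy means and between-bird SDs by age; suboptimal birds
    # add class_effects. Calibrated (deconvolved for keypoint measurement
    # noise and selection effects) so that the default pipeline's measured
    # output reproduces the study conditions' descriptive statistics.
    hock_angle_mean = pick(c(155.63, 156.89, 153.27)),
    hock_angle_sd = pick(c(1.55, 1.50, 4.69)),
    shank_angle_mean = pick(c(84.70, 85.94, 83.36)),
    shank_angle_sd = pick(c(2.19, 3.56, 5.13)),
    tibiotarsus_rel_mean = pick(c(0.632, 0.583, 0.577)),
    tibiotarsus_rel_sd = pick(c(0.010, 0.025, 0.033)),
    step_height_rel_mean = pick(c(37.51, 37.76, 36.62)),
    step_height_rel_sd = pick(c(5.97, 6.54, 9.32)),
    hock_feet_ratio_mean = pick(c(0.873, 0.893, 0.870)),
    hock_feet_ratio_sd = 0.06,
    hfdr_shank_slope = 0.0093,
    hfdr_resid_sd = 0.035,
    hock_knee_ratio_mean = pick(c(0.59, 0.62, 0.65)),
    hock_knee_ratio_sd = 0.07,
    shank_px_mean = pick(c(40, 52, 64)),
    shank_px_sd = pick(c(2.4, 3.1, 3.8)),
    tibiotarsus_px_mean = pick(c(45, 58, 72)),
    tibiotarsus_px_sd = pick(c(2.7, 3.5, 4.3)),
    foot_spread_px_mean = pick(c(61, 77, 112)),
    foot_spread_px_sd = pick(c(5, 6, 8)),
    # latent structure
    crouch_loading = 0.86,
    crouch_weight_share = 0.5,
    step_weight_share = 0.5,
    length_side_share = 0.5,
    extent_asym_sd = 0.05,
    ground_asym_sd_px = 5,
    # body weight
    weight_mean_g = pick(c(525, 1040, 2100)),
    weight_growth_cv = 0.08,
    weight_meas_sd_g = 15,
    # class effects: suboptimal minus good
    class_effects = list(hock_angle = -2.2, shank_angle = -1.3,
                         tibiotarsus_rel = 0.01, step_height_rel = -4.5,
                         hock_feet_ratio = -0.03,
                         body_weight_g = pick(c(9.7, 26.4, 64.3))),
    # rater model
    rater_bias = c(-0.3, -0.1, 0.1, 0.3),
    rater_sd = 0.40,
    rater_repeat_cor = 0.93,
    latent_good_mean = 1.35, latent_good_sd = 0.35,
    latent_subopt_mean = 2.85, latent_subopt_sd = 0.50,
    latent_nonwalker = 4.6
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown gait_params fields: ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  validate_gait_params(structure(p, class = "gait_params"))
}

validate_gait_params <- function(p) {
  sds <- p[grep("_sd$", names(p))]
  if (any(unlist(sds) < 0)) stop("all sd parameters must be >= 0")
  if (p$stance_fraction <= 0.5 || p$stance_fraction >= 1)
    stop("stance_fraction must lie in (0.5, 1) so double support exists")
  if (p$dropout_prob < 0 || p$dropout_prob > 1)
    stop("dropout_prob must lie in [0, 1]")
  if (p$hock_angle_mean <= p$shank_angle_mean)
    stop("infeasible geometry: hock angle must exceed shank angle")
  p
}

# Geometry of one leg in canonical frame: foot at (0, 0), lateral = +x,
# y down. Returns segment lengths and hock/knee offsets realizing the given
# hock angle, shank-floor angle and relative tibiotarsus length with total
# leg vertical extent N (so the normalization factor equals N exactly).
leg_geometry <- function(theta_h, theta_s, t_rel, N) {
  if (theta_h <= theta_s)
    stop("infeasible geometry: hock angle ", round(theta_h, 1),
         " not above shank angle ", round(theta_s, 1))
  th <- theta_h * pi / 180; ts <- theta_s * pi / 180
  a <- sin(ts)                  # shank vertical fraction
  b <- sin(th - ts)             # tibiotarsus vertical fraction
  if (b <= 0 || 1 - t_rel * b <= 0)
    stop("infeasible geometry: relative tibiotarsus length ", round(t_rel, 3),
         " cannot be realized at these angles")
  r <- t_rel * a / (1 - t_rel * b)   # tibiotarsus / shank length ratio
  s <- N / (a + b * r)
  t <- r * s
  hock <- c(-s * cos(ts), -s * a)
  knee <- hock + t * c(cos(ts - th), sin(ts - th))
  list(s = s, t = t, hock = hock, knee = knee)
}

# Build the double-support pose of one bird-age from its anatomy draw.
# The two feet rest at slightly different ground levels (litter is never
# flat), so the per-frame normalization factor mixes legs: lowest foot to
# highest knee. Returns leg keypoint coordinates (absolute px), the swing
# amplitudes in px, and the realized step heights (%).
build_pose_geometry <- function(an, center_x, ground_y) {
  gl <- leg_geometry(an$hock_angle[1], an$shank_angle[1], an$t_rel[1],
                     an$extent[1])
  gr <- leg_geometry(an$hock_angle[2], an$shank_angle[2], an$t_rel[2],
                     an$extent[2])
  half <- an$foot_spread / 2
  gy <- ground_y + an$ground_off
  # canonical lateral +x maps to -x for the left leg, +x for the right
  pos <- rbind(
    foot_left  = c(center_x - half, gy[1]),
    foot_right = c(center_x + half, gy[2]),
    hock_left  = c(center_x - half - gl$hock[1], gy[1] + gl$hock[2]),
    hock_right = c(center_x + half + gr$hock[1], gy[2] + gr$hock[2]),
    knee_left  = c(center_x - half - gl$knee[1], gy[1] + gl$knee[2]),
    knee_right = c(center_x + half + gr$knee[1], gy[2] + gr$knee[2]))
  colnames(pos) <- c("x", "y")
  if (pos["hock_right", "x"] <= pos["hock_left", "x"])
    stop("infeasible geometry: hocks cross the midline")
  nf <- max(pos[c("foot_left", "foot_right"), "y"]) -
    min(pos[c("knee_left", "knee_right"), "y"])
  # swing amplitude realizing the bird's step height against the grounded
  # other foot: step = (lift + other ground - own ground) / nf
  dg <- c(gy[2] - gy[1], gy[1] - gy[2])
  step_px <- pmax(1, an$step_rel / 100 * nf - dg)
  list(pos = pos, step_px = step_px,
       step_true = 100 * (step_px + dg) / nf)
}

# Ground-truth features of an anatomy draw, via the feature functions
# themselves on the noiseless double-support pose.
true_features_of <- function(an, params) {
  geom <- build_pose_geometry(an, params$frame_size[1] / 2, params$ground_y)
  pose <- structure(list(frame = 0L, kind = "double_support",
                         coords = geom$pos[leg_parts(), ]), class = "pose")
  tf <- pose_features(pose)[, c("feature", "side", "value")]
  rbind(tf, data.frame(feature = "step_height_rel", side = c("left", "right"),
                       value = geom$step_true))
}

#' Simulate a cohort of birds
#'
#' Draws per-bird anatomy from the population parameters (suboptimal birds
#' with the class effects added), body weights over the requested ages,
#' rear-view walking trials at each age, and 0-5 gait scores from 4 simulated
#' raters (including a 15-bird repeat-scoring arm). Good-class birds are
#' drawn so their mean score is at most 2 and suboptimal birds above 2.
#' Everything is reproducible from `seed`.
#'
#' @param n_good,n_suboptimal Number of birds per true gait class.
#' @param ages Ages (days) at which trials are simulated.
#' @param seed Integer seed; all randomness derives from it.
#' @param params Optional list of [gait_params()] per age (defaults built
#'   from `gait_params(age)`).
#' @param n_nonwalkers Number of additional birds that do not walk during the
#'   test (their leg keypoints never reach the likelihood threshold and they
#'   receive very poor gait scores).
#' @return A list of class `sim_cohort` with elements `birds` (per-bird
#'   metadata and ground-truth features), `trials` (list: bird, then age),
#'   `meta` (bird x age body weights and true class), `scores` (birds x 4
#'   raters), `repeat_scores` (the repeat arm) and `params`.
#' @export
simulate_cohort <- function(n_good, n_suboptimal, ages = c(14, 21, 33),
                            seed = 1, params = NULL, n_nonwalkers = 0) {
  stopifnot(n_good >= 0, n_suboptimal >= 0)
  if (is.null(params)) params <- lapply(ages, function(a) gait_params(a))
  names(params) <- as.character(ages)
  set.seed(seed)
  n <- n_good + n_suboptimal + n_nonwalkers
  if (n == 0) stop("empty cohort")
  classes <- rep(c("good", "suboptimal", "nonwalker"),
                 c(n_good, n_suboptimal, n_nonwalkers))
  birds <- vector("list", n)
  trials <- vector("list", n)
  meta <- list()
  for (bi in seq_len(n)) {
    bird <- draw_bird(sprintf("bird_%03d", bi), classes[bi], ages, params)
    trial_seeds <- sample.int(2^31 - 2, length(ages))
    tr <- list()
    for (j in seq_along(ages)) {
      a <- as.character(ages[j])
      tr[[a]] <- simulate_trial(params[[a]], bird, ages[j], trial_seeds[j])
    }
    birds[[bi]] <- bird
    trials[[bi]] <- tr
    meta[[bi]] <- data.frame(bird_id = bird$bird_id, age_days = ages,
                             body_weight_g = unlist(bird$weights),
                             group = "pen_1",
                             true_class = if (classes[bi] == "nonwalker")
                               "suboptimal" else classes[bi],
                             row.names = NULL)
  }
  names(trials) <- names(birds) <- vapply(birds, `[[`, "", "bird_id")
  sc <- simulate_scores(birds, params[[length(params)]])
  structure(list(birds = birds, trials = trials,
                 meta = do.call(rbind, meta),
                 scores = sc$scores, repeat_scores = sc$repeat_scores,
                 params = params, seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cl <- table(vapply(x$birds, `[[`, "", "class_label"))
  cat(sprintf("<sim_cohort> %d birds (%s), ages %s, seed %d\n",
              length(x$birds),
              paste(names(cl), cl, sep = ": ", collapse = ", "),
              paste(names(x$trials[[1]]), collapse = "/"), x$seed))
  invisible(x)
}

draw_bird <- function(bird_id, class_label, ages, params) {
  p1 <- params[[1]]
  eff <- if (class_label == "good") {
    list(hock_angle = 0, shank_angle = 0, tibiotarsus_rel = 0,
         step_height_rel = 0, hock_feet_ratio = 0, body_weight_g = 0)
  } else {
    p1$class_effects[c("hock_angle", "shank_angle", "tibiotarsus_rel",
                       "step_height_rel", "hock_feet_ratio")]
  }
  # bird-level latent draws, shared across ages
  growth <- stats::rnorm(1, 0, p1$weight_growth_cv)
  z_leg <- stats::rnorm(2)            # per-leg crouch component
  eps_hock <- stats::rnorm(2)
  eps_shank <- stats::rnorm(2)
  zeta_len_b <- stats::rnorm(1)
  zeta_len_leg <- stats::rnorm(2)
  eta_step <- stats::rnorm(2)
  xi_hfdr <- stats::rnorm(1)
  scale_z <- stats::rnorm(1)
  delta_extent <- stats::rnorm(2)
  anatomy <- list(); weights <- list()
  for (a in as.character(ages)) {
    p <- params[[a]]
    wt_class <- if (class_label == "good") 0 else p$class_effects$body_weight_g
    wt <- p$weight_mean_g * (1 + growth) + wt_class +
      stats::rnorm(1, 0, p$weight_meas_sd_g)
    weights[[a]] <- wt
    z_w <- (wt - p$weight_mean_g) / (p$weight_mean_g * p$weight_growth_cv)
    cw <- p$crouch_weight_share
    crouch <- cw * z_w + sqrt(1 - cw^2) * z_leg          # length 2 (per leg)
    lc <- p$crouch_loading
    hock <- p$hock_angle_mean + eff$hock_angle -
      p$hock_angle_sd * (lc * crouch + sqrt(1 - lc^2) * eps_hock)
    shank <- p$shank_angle_mean + eff$shank_angle -
      p$shank_angle_sd * (lc * crouch + sqrt(1 - lc^2) * eps_shank)
    ls <- p$length_side_share
    t_rel <- p$tibiotarsus_rel_mean + eff$tibiotarsus_rel +
      p$tibiotarsus_rel_sd * (sqrt(ls) * zeta_len_b + sqrt(1 - ls) * zeta_len_leg)
    sw <- p$step_weight_share
    step_rel <- pmax(1, p$step_height_rel_mean + eff$step_height_rel -
                       p$step_height_rel_sd * (sw * z_w + sqrt(1 - sw^2) * eta_step))
    # hock-feet ratio target: tracks the bird's shank angle with an
    # effective slope (crouched birds spread their feet relative to the
    # hocks), plus an independent stance-width component
    shank_cmean <- p$shank_angle_mean + eff$shank_angle
    hfdr <- p$hock_feet_ratio_mean + eff$hock_feet_ratio +
      p$hfdr_shank_slope * (mean(shank) - shank_cmean) +
      p$hfdr_resid_sd * xi_hfdr
    hfdr <- min(max(hfdr, 0.2), 1.5)
    # overall leg size: shank px draw sets the leg's vertical extent; the
    # two legs' extents differ slightly (stance and pelvis are never
    # perfectly level), so the higher knee alone sets the normalization
    s_b <- p$shank_px_mean + p$shank_px_sd * scale_z
    g0 <- leg_geometry(mean(hock), mean(shank), mean(t_rel), 1)
    N <- s_b * (1 / g0$s)               # extent implied by shank length s_b
    extent <- N * (1 + p$extent_asym_sd * delta_extent)
    # foot spread realizing the bird's target hock-feet ratio at its own
    # mean shank geometry, clamped to a feasible stance width
    g <- 2 * s_b * cos(mean(shank) * pi / 180)
    spread <- if (abs(g) < 0.04 * s_b || hfdr >= 1) p$foot_spread_px_mean
              else g / (1 - hfdr)
    spread <- min(max(spread, 0.4 * s_b), 4 * s_b)
    anatomy[[a]] <- list(hock_angle = hock, shank_angle = shank,
                         t_rel = t_rel, step_rel = step_rel,
                         extent = extent, N = max(extent),
                         ground_off = stats::rnorm(2, 0, p$ground_asym_sd_px),
                         foot_spread = spread, hfdr_target = hfdr)
  }
  truth <- lapply(anatomy, true_features_of, params = params[[1]])
  list(bird_id = bird_id, class_label = class_label, walks = class_label != "nonwalker",
       anatomy = anatomy, weights = weights, true_features = truth,
       growth = growth)
}

#' Simulate one walking trial
#'
#' Synthesizes the rear-view keypoint trajectories of one bird at one age:
#' feet alternate stance (constant ground level) and swing (half-sine lift
#' scaled so the true relative step height is realized exactly at the swing
#' apex, which falls on a sampled frame), hocks and knees placed from the
#' bird's double-support geometry, whole-body lateral sway, Gaussian pixel
#' noise, and likelihood dropout. Deterministic given (params, bird, seed).
#'
#' @param params A [gait_params()] for this age.
#' @param bird A bird as drawn by [simulate_cohort()].
#' @param age_days Age of the trial.
#' @param seed Integer seed.
#' @return A [tracked_trial()].
#' @export
simulate_trial <- function(params, bird, age_days, seed = 1) {
  a <- as.character(age_days)
  if (!a %in% names(bird$anatomy)) stop("bird has no anatomy at age ", age_days)
  an <- bird$anatomy[[a]]
  set.seed(seed %% (2^31 - 1))
  fps <- params$fps
  P <- round(params$stride_period_s * fps)
  n_sw <- round((1 - params$stance_fraction) * P)
  if (n_sw %% 2 == 0) n_sw <- n_sw + 1L     # odd: the swing apex is sampled
  if (n_sw >= P / 2) stop("infeasible gait: swing longer than half a stride")
  n <- round(params$trial_s * fps)
  cx <- params$frame_size[1] / 2
  geom <- build_pose_geometry(an, cx, params$ground_y)
  pos <- geom$pos
  frames <- 0:(n - 1)
  phase0 <- sample.int(P, 1) - 1L
  cyc_l <- (frames + phase0) %% P
  cyc_r <- (frames + phase0 + P %/% 2) %% P
  lift_profile <- function(c) ifelse(c < n_sw, sin(pi * (c + 0.5) / n_sw), 0)
  lift_l <- lift_profile(cyc_l) * geom$step_px[1]
  lift_r <- lift_profile(cyc_r) * geom$step_px[2]
  if (!bird$walks) lift_l <- lift_r <- rep(0, n)
  sway <- params$lateral_sway_px * sin(2 * pi * (frames + phase0) / P)
  x <- y <- matrix(0, n, 8, dimnames = list(NULL, body_parts()))
  for (part in leg_parts()) {
    x[, part] <- pos[part, "x"]
    y[, part] <- pos[part, "y"]
  }
  y[, "foot_left"] <- y[, "foot_left"] - lift_l
  y[, "foot_right"] <- y[, "foot_right"] - lift_r
  y[, "hock_left"] <- y[, "hock_left"] - 0.5 * lift_l
  y[, "hock_right"] <- y[, "hock_right"] - 0.5 * lift_r
  x[, "neck"] <- cx; y[, "neck"] <- params$ground_y - 1.35 * an$N
  x[, "head"] <- cx; y[, "head"] <- params$ground_y - 1.7 * an$N
  if (params$scale_drift_per_s > 0) {
    shrink <- 1 - params$scale_drift_per_s * frames / fps
    x <- cx + (x - cx) * shrink
    y <- params$ground_y + (y - params$ground_y) * shrink
  }
  x <- x + sway
  if (params$knee_bias_sd_px > 0) {
    # the knee sits under a thick feather layer: the pose model localizes it
    # with a bird-specific systematic offset that persists across the frames
    # of a recording, on top of the frame-level jitter
    for (part in c("knee_left", "knee_right")) {
      x[, part] <- x[, part] + stats::rnorm(1, 0, params$knee_bias_sd_px)
      y[, part] <- y[, part] + stats::rnorm(1, 0, params$knee_bias_sd_px)
    }
  }
  if (params$noise_sd_px > 0) {
    # frame-level detection jitter, inflated for the feather-covered knees
    sd_part <- rep(params$noise_sd_px, 8)
    sd_part[match(c("knee_left", "knee_right"), body_parts())] <-
      params$noise_sd_px * params$knee_noise_mult
    sd_mat <- matrix(sd_part, n, 8, byrow = TRUE)
    x <- x + matrix(stats::rnorm(n * 8, 0, sd_mat), n, 8)
    y <- y + matrix(stats::rnorm(n * 8, 0, sd_mat), n, 8)
  }
  tau <- params$likelihood_threshold
  lik <- matrix(stats::runif(n * 8, tau, 1), n, 8,
                dimnames = list(NULL, body_parts()))
  drop_legs <- matrix(stats::runif(n * 6) < params$dropout_prob, n, 6)
  if (!bird$walks) drop_legs[] <- TRUE     # legs occluded while sitting
  lik[, leg_parts()][drop_legs] <- stats::runif(sum(drop_legs), 0, tau - 0.01)
  drop_hn <- matrix(stats::runif(n * 2) < params$dropout_prob_headneck, n, 2)
  lik[, c("head", "neck")][drop_hn] <- stats::runif(sum(drop_hn), 0, tau - 0.01)
  tracked_trial(x, y, lik, bird_id = bird$bird_id, age_days = age_days,
                fps = fps, frame_size = params$frame_size,
                start_frame = 0L, end_frame = n - 1L)
}

# Draw the 4-rater score table plus the 15-bird repeat arm. Good birds are
# guaranteed a mean score <= 2, suboptimal birds > 2 (resampling, with a
# deterministic fallback).
simulate_scores <- function(birds, params) {
  n <- length(birds)
  nr <- length(params$rater_bias)
  scores <- matrix(NA_integer_, n, nr,
                   dimnames = list(names(birds), paste0("rater_", LETTERS[1:nr])))
  latents <- numeric(n)
  err <- matrix(0, n, nr)
  for (i in seq_len(n)) {
    cl <- birds[[i]]$class_label
    l <- switch(cl,
                good = stats::rnorm(1, params$latent_good_mean, params$latent_good_sd),
                suboptimal = stats::rnorm(1, params$latent_subopt_mean,
                                          params$latent_subopt_sd),
                nonwalker = params$latent_nonwalker + stats::rnorm(1, 0, 0.2))
    for (try in 1:100) {
      e <- stats::rnorm(nr, 0, params$rater_sd)
      s <- pmin(5L, pmax(0L, as.integer(round(l + params$rater_bias + e))))
      m <- mean(s)
      ok <- switch(cl, good = m <= 2, suboptimal = m > 2, nonwalker = m >= 4.25)
      if (ok) break
    }
    if (!ok) {
      s <- switch(cl, good = rep(2L, nr), suboptimal = rep(3L, nr),
                  nonwalker = rep(5L, nr))
      e <- rep(0, nr)
    }
    scores[i, ] <- s
    latents[i] <- l
    err[i, ] <- e
  }
  idx <- sample(n, min(15, n))
  rep2 <- matrix(NA_integer_, length(idx), nr,
                 dimnames = list(rownames(scores)[idx], colnames(scores)))
  rc <- params$rater_repeat_cor
  for (j in seq_along(idx)) {
    i <- idx[j]
    e2 <- rc * err[i, ] + sqrt(1 - rc^2) * stats::rnorm(nr, 0, params$rater_sd)
    rep2[j, ] <- pmin(5L, pmax(0L, as.integer(round(latents[i] +
                                                      params$rater_bias + e2))))
  }
  list(scores = scores,
       repeat_scores = list(pass1 = scores[idx, , drop = FALSE], pass2 = rep2))
}
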