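test_that("normalization factor is the lowest-foot-to-highest-knee distance", {
  pose <- make_pose()
  pose$coords["knee_left", "y"] <- 205
  expect_equal(normalization_factor(pose), 330 - 200)
  inverted <- make_pose()
  inverted$coords[c("knee_left", "knee_right"), "y"] <- 400
  inverted$coords[c("foot_left", "foot_right"), "y"] <- 100
  expect_error(normalization_factor(inverted), "degenerate")
  set.seed(1)
  for (i in 1:20) {
    p <- make_pose()
    p$coords[, "y"] <- p$coords[, "y"] + rnorm(6, 0, 10)
    nf <- try(normalization_factor(p), silent = TRUE)
    brute <- max(p$coords[c("foot_left", "foot_right"), "y"]) -
      min(p$coords[c("knee_left", "knee_right"), "y"])
    if (brute > 0) expect_equal(nf, brute)
  }
})

test_that("hock joint angle follows the dot-product formula", {
  pose <- make_pose()
  # right leg: knee (100,200), hock (110,260), foot (105,330)
  expect_equal(hock_joint_angle(pose, "right"), 166.4, tolerance = 5e-4)
  collinear <- make_pose()
  collinear$coords["knee_right", ] <- c(110, 200)
  collinear$coords["foot_right", ] <- c(110, 330)
  expect_equal(hock_joint_angle(collinear, "right"), 180)
  degenerate <- make_pose()
  degenerate$coords["knee_right", ] <- degenerate$coords["hock_right", ]
  expect_error(hock_joint_angle(degenerate, "right"), "degenerate")
  expect_error(hock_joint_angle(make_pose("step_left"), "right"), "kind")
})

test_that("shank-vs-floor angle is measured toward the midline", {
  # feet x {130, 190}; right foot (190, 330), right hock (180, 260)
  coords <- rbind(knee_left = c(120, 200), knee_right = c(185, 200),
                  hock_left = c(140, 260), hock_right = c(180, 260),
                  foot_left = c(130, 330), foot_right = c(190, 330))
  colnames(coords) <- c("x", "y")
  pose <- make_pose(coords = coords)
  expect_equal(shank_floor_angle(pose, "right"), 81.9, tolerance = 5e-4)
  vertical <- make_pose(coords = coords)
  vertical$coords["hock_right", "x"] <- 190
  expect_equal(shank_floor_angle(vertical, "right"), 90)
  coincident <- make_pose(coords = coords)
  coincident$coords["foot_left", "x"] <- 190
  expect_error(shank_floor_angle(coincident, "right"), "midline")
})

test_that("relative segment lengths are lengths over the normalization factor", {
  pose <- make_pose()   # right: knee (100,200) hock (110,260) foot (105,330), N=130
  rel <- relative_segment_lengths(pose, "right")
  expect_equal(unname(rel["tibiotarsus_rel"]), sqrt(10^2 + 60^2) / 130,
               tolerance = 1e-9)
  expect_equal(unname(rel["tibiotarsus_rel"]), 0.468, tolerance = 5e-4)
  # vertical fully stretched leg: segments sum to the normalization factor
  coords <- rbind(knee_left = c(-100, 200), knee_right = c(100, 200),
                  hock_left = c(-100, 260), hock_right = c(100, 260),
                  foot_left = c(-100, 330), foot_right = c(100, 330))
  colnames(coords) <- c("x", "y")
  straight <- make_pose(coords = coords)
  rel2 <- relative_segment_lengths(straight, "left")
  expect_equal(sum(rel2), 1)
})

test_that("horizontal distance ratios follow the arithmetic and mirror invariance", {
  coords <- rbind(knee_left = c(130, 200), knee_right = c(195, 200),
                  hock_left = c(140, 260), hock_right = c(180, 260),
                  foot_left = c(120, 330), foot_right = c(200, 330))
  colnames(coords) <- c("x", "y")
  pose <- make_pose(coords = coords)
  expect_equal(hock_knee_ratio(pose), 40 / 65, tolerance = 1e-9)
  expect_equal(hock_feet_ratio(pose), 40 / 80, tolerance = 1e-9)
  hf <- make_pose()
  hf$coords[c("hock_left", "hock_right"), "x"] <- c(-40, 40)
  hf$coords[c("foot_left", "foot_right"), "x"] <- c(-50, 50)
  expect_equal(hock_feet_ratio(hf), 0.8)
  mirrored <- make_pose(coords = coords)
  mirrored$coords[, "x"] <- 1280 - mirrored$coords[, "x"]
  expect_equal(hock_knee_ratio(mirrored), hock_knee_ratio(pose))
  expect_equal(hock_feet_ratio(mirrored), hock_feet_ratio(pose))
  flat <- make_pose(coords = coords)
  flat$coords[c("knee_left", "knee_right"), "x"] <- 0
  expect_error(hock_knee_ratio(flat), "degenerate")
})

test_that("step height is the normalized feet difference with warning on negatives", {
  coords <- rbind(knee_left = c(-100, 200), knee_right = c(100, 200),
                  hock_left = c(-110, 250), hock_right = c(110, 260),
                  foot_left = c(-105, 283), foot_right = c(105, 330))
  colnames(coords) <- c("x", "y")
  pose <- make_pose("step_left", coords = coords)
  expect_equal(step_height(pose), 100 * 47 / 130, tolerance = 1e-9)
  expect_equal(step_height(pose), 36.15, tolerance = 2e-3)
  level <- make_pose("step_right")
  expect_equal(step_height(level), 0)
  neg <- make_pose("step_left", coords = coords)
  neg$coords["foot_left", "y"] <- 340
  neg$coords["foot_right", "y"] <- 330
  expect_warning(val <- step_height(neg), "negative")
  expect_lt(val, 0)
})

test_that("all features are translation and scale invariant", {
  co <- simulate_cohort(1, 0, ages = 33, seed = 61)
  tr <- clip_trial(co$trials[[1]][["33"]])
  tr <- mask_low_likelihood(trim_edges(tr, cleaning_config()), cleaning_config())
  ps <- extract_poses(tr, config = pose_config())
  for (po in ps$poses[c(1, 4, 7)]) {
    base <- pose_features(po)
    shifted <- po; shifted$coords <- po$coords + 37.5
    expect_equal(pose_features(shifted)$value, base$value, tolerance = 1e-9)
    scaled <- po; scaled$coords <- po$coords * 2.3
    expect_equal(pose_features(scaled)$value, base$value, tolerance = 1e-9)
  }
})

test_that("left-right mirroring swaps side features exactly", {
  co <- simulate_cohort(1, 0, ages = 33, seed = 62)
  tr <- clip_trial(co$trials[[1]][["33"]])
  tr <- mask_low_likelihood(trim_edges(tr, cleaning_config()), cleaning_config())
  ps <- extract_poses(tr, config = pose_config())
  po <- ps$poses[[1]]
  mir <- po
  mir$coords[, "x"] <- -po$coords[, "x"]
  swap <- c(knee_left = "knee_right", knee_right = "knee_left",
            hock_left = "hock_right", hock_right = "hock_left",
            foot_left = "foot_right", foot_right = "foot_left")
  mir$coords <- mir$coords[swap[rownames(mir$coords)], ]
  rownames(mir$coords) <- names(swap[rownames(po$coords)])
  mir$coords <- mir$coords[leg_parts(), ]
  for (side in c("left", "right")) {
    other <- setdiff(c("left", "right"), side)
    expect_equal(hock_joint_angle(mir, side), hock_joint_angle(po, other),
                 tolerance = 1e-9)
    expect_equal(shank_floor_angle(mir, side), shank_floor_angle(po, other),
                 tolerance = 1e-9)
  }
  expect_equal(hock_feet_ratio(mir), hock_feet_ratio(po), tolerance = 1e-9)
})

test_that("aggregation averages per feature-side over available frames", {
  poses <- lapply(c(10L, 20L, 30L), function(f) make_pose(frame = f))
  ps <- structure(list(bird_id = "b", age_days = 33L, poses = poses,
                       failures = character(0)), class = "pose_set")
  agg <- aggregate_features(ps)
  expect_true(all(agg$n_frames == 3))
  one <- pose_features(poses[[1]])
  m <- merge(agg, one, by = c("feature", "side"))
  expect_equal(m$value.x, m$value.y)        # identical frames: mean == single
  ps1 <- structure(list(bird_id = "b", age_days = 33L,
                        poses = poses[1], failures = character(0)),
                   class = "pose_set")
  agg1 <- aggregate_features(ps1)
  expect_true(all(agg1$n_frames == 1))
  expect_false("step_height_rel" %in% agg1$feature)   # missing kind absent
  # random poses: brute-force mean oracle
  set.seed(3)
  rposes <- lapply(1:3, function(i) {
    p <- make_pose(frame = i)
    p$coords <- p$coords + rnorm(12, 0, 4)
    p
  })
  psr <- structure(list(bird_id = "b", age_days = 33L, poses = rposes,
                        failures = character(0)), class = "pose_set")
  aggr <- aggregate_features(psr)
  hl <- vapply(rposes, hock_joint_angle, 0, side = "left")
  expect_equal(aggr$value[aggr$feature == "hock_joint_angle" &
                            aggr$side == "left"], mean(hl), tolerance = 1e-9)
})

test_that("noiseless simulation and feature extraction are inverse-consistent", {
  co <- noiseless_trial(seed = 7, n_good = 2, n_sub = 1)
  for (bid in names(co$trials)) {
    rec <- extract_trial_features(co$trials[[bid]][["33"]],
                                  cleaning_config(), pose_config())
    truth <- co$birds[[bid]]$true_features[["33"]]
    m <- merge(rec, truth, by = c("feature", "side"),
               suffixes = c("_est", "_true"))
    expect_equal(nrow(m), 12L)
    rel_err <- abs(m$value_est - m$value_true) / pmax(abs(m$value_true), 1e-9)
    expect_lt(max(rel_err), 1e-6)
  }
})
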