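make_records <- function(n_good = 30, n_sub = 20, effect = 0, seed = 1,
                         feature = "hock_joint_angle", sd = 5,
                         weight_slope = 0) {
  set.seed(seed)
  n <- n_good + n_sub
  ids <- sprintf("b%03d", seq_len(n))
  cls <- rep(c("good", "suboptimal"), c(n_good, n_sub))
  wt <- rnorm(n, 2000, 150)
  bird_mean <- 150 + effect * (cls == "suboptimal") + weight_slope * (wt - 2000)
  rec <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(bird_id = ids[i], age_days = 33L, feature = feature,
               side = c("left", "right"),
               value = bird_mean[i] + rnorm(2, 0, sd), n_frames = 3L)))
  meta <- data.frame(bird_id = ids, age_days = 33L, body_weight_g = wt,
                     gait_class = cls)
  list(records = rec, meta = meta)
}

test_that("2xIQR screen uses type-7 quartiles and keeps the bulk", {
  keep <- remove_outliers(c(1, 2, 3, 4, 100))
  expect_equal(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))  # bounds [-2, 8]
  expect_true(all(remove_outliers(rep(7, 10))))
  expect_warning(k3 <- remove_outliers(c(1, 2, 3)), "fewer than 4")
  expect_true(all(k3))
})

test_that("the outlier screen is idempotent on the kept set", {
  set.seed(8)
  for (i in 1:10) {
    x <- c(rnorm(50), rnorm(3, 0, 20))
    k1 <- remove_outliers(x)
    k2 <- remove_outliers(x[k1])
    expect_true(all(k2))
  }
})

test_that("uncontaminated cohorts essentially never lose records to the screen", {
  # for Gaussian data the 2xIQR fences sit at about +-3.4 SD, so removals
  # are rare: most replicates lose nothing and the removal rate is far
  # below one record per thousand
  set.seed(15)
  losses <- replicate(60, {
    x <- rnorm(164)
    sum(!remove_outliers(x))
  })
  expect_gte(mean(losses == 0), 0.80)
  expect_lt(mean(losses) / 164, 0.002)
})

test_that("filter_outliers screens within age-feature groups pooling sides", {
  d <- make_records(seed = 3)
  d$records$value[1] <- 1e5
  out <- filter_outliers(d$records)
  expect_equal(attr(out, "n_removed"), 1L)
  expect_false(1e5 %in% out$value)
})

test_that("the class model collapses to a mean difference in the balanced null case", {
  d <- make_records(n_good = 25, n_sub = 25, effect = -3, seed = 5, sd = 1e-6)
  est <- feature_class_model(d$records, d$meta, "hock_joint_angle")
  expect_equal(est$diff, -3, tolerance = 1e-3)
  expect_equal(est$value_at_good, 150, tolerance = 1e-3)
  expect_equal(est$pct_diff, 100 * est$diff / est$value_at_good)
})

test_that("type-I error of the class model is near the nominal level under the null", {
  ps <- vapply(1:200, function(i) {
    d <- make_records(n_good = 20, n_sub = 16, effect = 0, seed = 1000 + i)
    feature_class_model(d$records, d$meta, "hock_joint_angle")$p
  }, 0)
  rate <- mean(ps <= 0.05)
  # binomial 99% band around 0.05 with 200 draws
  expect_gt(rate, 0.05 - 2.58 * sqrt(0.05 * 0.95 / 200) - 1e-9)
  expect_lt(rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 200) + 0.02)
})

test_that("the interaction term is dropped only when non-significant", {
  d <- make_records(n_good = 40, n_sub = 40, effect = -2, seed = 9)
  # inject a strong class-by-side interaction
  idx <- d$records$side == "right" &
    d$records$bird_id %in% d$meta$bird_id[d$meta$gait_class == "suboptimal"]
  d$records$value[idx] <- d$records$value[idx] + 25
  est <- feature_class_model(d$records, d$meta, "hock_joint_angle")
  expect_lte(est$interaction_p, 0.05)
  d2 <- make_records(n_good = 40, n_sub = 40, effect = -2, seed = 10)
  est2 <- feature_class_model(d2$records, d2$meta, "hock_joint_angle")
  expect_gt(est2$interaction_p, 0.05)
  expect_equal(est2$diff, -2, tolerance = 1.5)
})

test_that("ratio models use one record per bird and match a normal-equations oracle", {
  set.seed(21)
  n <- 10
  ids <- sprintf("b%02d", 1:n)
  cls <- rep(c("good", "suboptimal"), each = 5)
  wt <- rnorm(n, 2000, 100)
  val <- 0.85 - 0.03 * (cls == "suboptimal") + rnorm(n, 0, 0.02)
  rec <- data.frame(bird_id = ids, age_days = 33L, feature = "hock_feet_ratio",
                    side = "none", value = val, n_frames = 3L)
  meta <- data.frame(bird_id = ids, age_days = 33L, body_weight_g = wt,
                     gait_class = cls)
  est <- ratio_class_model(rec, meta, "hock_feet_ratio")
  X <- cbind(1, cls == "suboptimal", wt)
  beta <- solve(t(X) %*% X, t(X) %*% val)
  expect_equal(est$diff, beta[2], tolerance = 1e-9)
  one_class <- meta; one_class$gait_class <- "good"
  expect_error(ratio_class_model(rec, one_class, "hock_feet_ratio"),
               "inestimable")
})

test_that("percentage difference is the plain ratio and guards a zero baseline", {
  expect_equal(percent_difference(-2.2, 152.9), 100 * -2.2 / 152.9)
  expect_equal(percent_difference(-2.2, 152.9), -1.44, tolerance = 5e-3)
  expect_equal(percent_difference(0, 3), 0)
  expect_equal(percent_difference(3, 3), 100)
  expect_error(percent_difference(1, 0), "zero baseline")
})

test_that("feature correlations average sides first and match the closed form", {
  rec <- rbind(
    data.frame(bird_id = sprintf("b%d", 1:5), age_days = 33L,
               feature = "hock_joint_angle", side = "left",
               value = c(150, 152, 154, 156, 158), n_frames = 3L),
    data.frame(bird_id = sprintf("b%d", 1:5), age_days = 33L,
               feature = "shank_floor_angle", side = "left",
               value = c(80, 81, 84, 83, 88), n_frames = 3L))
  out <- feature_correlations(rec)
  x <- c(150, 152, 154, 156, 158); y <- c(80, 81, 84, 83, 88)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r["hock_joint_angle", "shank_floor_angle"], r_hand)
  expect_equal(out$p["hock_joint_angle", "shank_floor_angle"],
               cor.test(x, y)$p.value)
  perfect <- rec
  perfect$value[perfect$feature == "shank_floor_angle"] <- x
  expect_equal(feature_correlations(perfect)$r[1, 2], 1)
})

test_that("the exchangeable GEE reproduces an independent reference fit", {
  # 8 birds x 3 ages; expected values computed once with an independent
  # GEE implementation (exchangeable working correlation, robust errors)
  df <- read.csv(text = "bird,age,cls,w
b0,14,good,509.02387379312825
b0,21,good,991.8373720070076
b0,33,good,1973.343752505156
b1,14,good,447.51706409152
b1,21,good,979.070768819337
b1,33,good,2017.4729181080495
b2,14,good,456.7754270778353
b2,21,good,990.0849355779894
b2,33,good,1986.0962843172356
b3,14,good,477.3566711086488
b3,21,good,1004.3931577759968
b3,33,good,2026.129808283644
b4,14,sub,439.0607998045393
b4,21,sub,915.7525904417206
b4,33,sub,1954.1031404421965
b5,14,sub,420.860514178173
b5,21,sub,909.8898536671024
b5,33,sub,1976.0511788750644
b6,14,sub,522.2296259923127
b6,21,sub,972.334763006596
b6,33,sub,2051.6767674558123
b7,14,sub,520.9742223100457
b7,21,sub,991.6708797647844
b7,33,sub,2043.2423544489284")
  df$gait_class <- ifelse(df$cls == "sub", "suboptimal", "good")
  names(df)[names(df) == "w"] <- "body_weight_g"
  names(df)[names(df) == "age"] <- "age_days"
  names(df)[names(df) == "bird"] <- "bird_id"
  fit <- gaitpose:::gee_exchangeable(
    body_weight_g ~ factor(age_days) * factor(gait_class), df, id = df$bird_id)
  expect_equal(unname(fit$coefficients),
               c(472.668259, 518.678300, 1528.092432, 3.113032,
                 -47.047568, 2.394638), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               c(11.802745, 10.416308, 19.762156, 25.972836,
                 12.571150, 21.163242), tolerance = 1e-5)
  bw <- bodyweight_class_contrast(df)
  expect_equal(bw$diff, c(3.113032, 3.113032 - 47.047568, 3.113032 + 2.394638),
               tolerance = 1e-6)
})

test_that("with independent observations the GEE contrast equals the OLS coefficient", {
  set.seed(31)
  meta <- data.frame(bird_id = sprintf("b%02d", 1:40), age_days = 33L,
                     body_weight_g = rnorm(40, 2000, 150),
                     gait_class = rep(c("good", "suboptimal"), each = 20))
  bw <- bodyweight_class_contrast(meta)
  ols <- lm(body_weight_g ~ gait_class, data = meta)
  expect_equal(bw$diff, unname(coef(ols)["gait_classsuboptimal"]),
               tolerance = 1e-8)
})

test_that("significance labels use the printed inclusive boundaries", {
  expect_equal(significance_label(0.042), "significant")
  expect_equal(significance_label(0.05), "significant")
  expect_equal(significance_label(0.051), "tendency")
  expect_equal(significance_label(0.100), "tendency")
  expect_equal(significance_label(0.5), "ns")
  expect_error(significance_label(1.5))
})
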