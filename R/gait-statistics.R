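#' Analysis configuration
#'
#' @param iqr_multiplier Multiple of the interquartile range beyond the
#'   quartiles outside which a value is an outlier (default 2).
#' @param alpha Significance level (default 0.05).
#' @param tendency_upper Upper bound of the tendency band (default 0.10):
#'   `alpha < P <= tendency_upper` counts as a tendency.
#' @param cutoff Mean-gait-score cutoff for the binary class (default 2).
#' @param analysis_age Age (days) at which class differences are analyzed
#'   (default 33).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(iqr_multiplier = 2, alpha = 0.05,
                            tendency_upper = 0.10, cutoff = 2.0,
                            analysis_age = 33L) {
  if (iqr_multiplier <= 0) stop("iqr_multiplier must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (tendency_upper <= alpha) stop("tendency_upper must exceed alpha")
  structure(list(iqr_multiplier = iqr_multiplier, alpha = alpha,
                 tendency_upper = tendency_upper, cutoff = cutoff,
                 analysis_age = as.integer(analysis_age)),
            class = "analysis_config")
}

#' Interquartile-range outlier screen
#'
#' Keeps x if it lies within `[Q1 - m*IQR, Q3 + m*IQR]` with m the
#' configured multiplier (default 2) and quartiles by linear interpolation
#' (type 7). With fewer than 4 values no screening is done (warning).
#'
#' @param values Numeric vector.
#' @param config An [analysis_config()].
#' @return Logical keep mask.
#' @export
remove_outliers <- function(values, config = analysis_config()) {
  ok <- is.finite(values)
  if (sum(ok) < 4) {
    warning("fewer than 4 values; outlier screen skipped")
    return(ok)
  }
  q <- stats::quantile(values[ok], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - config$iqr_multiplier * iqr
  hi <- q[2] + config$iqr_multiplier * iqr
  ok & values >= lo & values <= hi
}

#' Screen feature records for outliers
#'
#' Applies [remove_outliers()] within each age x feature combination,
#' pooling sides, and drops the flagged records.
#'
#' @param records Feature records from [aggregate_features()].
#' @param config An [analysis_config()].
#' @return The records with outliers removed; the number dropped per group is
#'   attached as attribute `n_removed`.
#' @export
filter_outliers <- function(records, config = analysis_config()) {
  grp <- interaction(records$age_days, records$feature, drop = TRUE)
  keep <- rep(TRUE, nrow(records))
  for (g in levels(grp)) {
    idx <- which(grp == g)
    keep[idx] <- suppressWarnings(remove_outliers(records$value[idx], config))
  }
  out <- records[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

effect_row <- function(feature, fit, data, config, interaction_p = NA_real_) {
  co <- stats::coef(fit)
  # reported difference: the side-averaged (marginal) class effect. With the
  # interaction dropped this is the class coefficient; if the interaction is
  # retained, the class coefficient alone is the left-side effect, so half
  # the interaction coefficient is added.
  L <- stats::setNames(numeric(length(co)), names(co))
  L["gait_classsuboptimal"] <- 1
  if ("gait_classsuboptimal:sideright" %in% names(co))
    L["gait_classsuboptimal:sideright"] <- 0.5
  diff <- unname(sum(L * co))
  se <- sqrt(drop(t(L) %*% stats::vcov(fit) %*% L))
  dfree <- stats::df.residual(fit)
  ci <- diff + c(-1, 1) * stats::qt(0.975, dfree) * se
  p <- 2 * stats::pt(-abs(diff / se), dfree)
  newd <- data.frame(gait_class = factor("good", levels = c("good", "suboptimal")),
                     body_weight_g = mean(data$body_weight_g))
  if ("side" %in% names(fit$model)) {
    newd <- merge(newd, data.frame(side = factor(c("left", "right"))))
    vag <- mean(stats::predict(fit, newdata = newd))
  } else {
    vag <- stats::predict(fit, newdata = newd)
  }
  pct <- percent_difference(diff, vag)
  data.frame(feature = feature, value_at_good = unname(vag), diff = diff,
             ci_low = ci[1], ci_high = ci[2], p = p,
             pct_diff = pct, pct_low = 100 * ci[1] / vag,
             pct_high = 100 * ci[2] / vag,
             interaction_p = interaction_p, row.names = NULL)
}

assemble_model_data <- function(records, meta, feature, config) {
  rec <- records[records$feature == feature &
                   records$age_days == config$analysis_age, , drop = FALSE]
  m <- meta[meta$age_days == config$analysis_age,
            c("bird_id", "body_weight_g", "gait_class")]
  dat <- merge(rec, m, by = "bird_id")
  dat$gait_class <- factor(dat$gait_class, levels = c("good", "suboptimal"))
  if (length(unique(dat$gait_class[!is.na(dat$value)])) < 2)
    stop("class contrast inestimable: only one gait class present")
  dat
}

#' Class-difference model for a sided pose feature
#'
#' Ordinary least squares on the side-level records of one feature at the
#' analysis age: `value ~ gait_class + body_weight_g + side +
#' gait_class:side`. If the class-by-side interaction is not significant at
#' `alpha` it is removed and the model refitted; the reported class
#' coefficient (suboptimal minus good), its 95% CI and P come from the final
#' fit. The value at good gait is the model-implied good-class mean at the
#' mean body weight, averaged over sides, and the percentage difference and
#' its CI are the class coefficient and CI divided by that baseline.
#'
#' @param records Outlier-screened feature records.
#' @param meta Data frame with `bird_id`, `age_days`, `body_weight_g`,
#'   `gait_class`.
#' @param feature A sided feature name.
#' @param config An [analysis_config()].
#' @return One-row data frame (the effect estimate).
#' @export
feature_class_model <- function(records, meta, feature,
                                config = analysis_config()) {
  dat <- assemble_model_data(records, meta, feature, config)
  dat$side <- factor(dat$side, levels = c("left", "right"))
  fit_int <- stats::lm(value ~ gait_class + body_weight_g + side +
                         gait_class:side, data = dat)
  p_int <- stats::coef(summary(fit_int))["gait_classsuboptimal:sideright",
                                         "Pr(>|t|)"]
  fit <- if (is.finite(p_int) && p_int <= config$alpha) fit_int else
    stats::lm(value ~ gait_class + body_weight_g + side, data = dat)
  effect_row(feature, fit, dat, config, interaction_p = p_int)
}

#' Class-difference model for an unsided ratio feature
#'
#' As [feature_class_model()], but for the hock-knee and hock-feet distance
#' ratios, which have one record per bird: `value ~ gait_class +
#' body_weight_g`.
#'
#' @inheritParams feature_class_model
#' @export
ratio_class_model <- function(records, meta, feature,
                              config = analysis_config()) {
  dat <- assemble_model_data(records, meta, feature, config)
  fit <- stats::lm(value ~ gait_class + body_weight_g, data = dat)
  effect_row(feature, fit, dat, config)
}

#' Percentage difference of a class effect
#'
#' `100 * diff / value_at_good`, computed from unrounded model outputs.
#'
#' @param diff Class difference (suboptimal minus good) in feature units.
#' @param value_at_good Model-implied feature value at good gait.
#' @return Percent difference.
#' @export
percent_difference <- function(diff, value_at_good) {
  if (!is.finite(value_at_good) || value_at_good == 0)
    stop("percentage difference undefined: zero baseline")
  100 * diff / value_at_good
}

#' Pairwise Pearson correlations among features
#'
#' Averages sides within bird first, then correlates features across birds
#' at the analysis age, with two-sided P values from the t transform.
#'
#' @param records Feature records.
#' @param config An [analysis_config()].
#' @return List with matrices `r`, `p` and `n`.
#' @export
feature_correlations <- function(records, config = analysis_config()) {
  rec <- records[records$age_days == config$analysis_age, , drop = FALSE]
  byb <- stats::aggregate(value ~ bird_id + feature, data = rec, FUN = mean)
  wide <- stats::reshape(byb, idvar = "bird_id", timevar = "feature",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^value\\.", "", colnames(mat))
  if (nrow(mat) < 3) stop("at least 3 birds required for correlations")
  feats <- colnames(mat)
  r <- p <- n <- matrix(NA_real_, length(feats), length(feats),
                        dimnames = list(feats, feats))
  for (i in seq_along(feats)) for (j in seq_along(feats)) {
    ok <- is.finite(mat[, i]) & is.finite(mat[, j])
    n[i, j] <- sum(ok)
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    if (n[i, j] >= 3 && stats::sd(mat[ok, i]) > 0 && stats::sd(mat[ok, j]) > 0) {
      ct <- stats::cor.test(mat[ok, i], mat[ok, j], method = "pearson")
      r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, n = n)
}

# Gaussian generalized estimating equations with exchangeable working
# correlation and robust (sandwich) covariance. Clusters need not be
# balanced. Returns coefficients and the robust vcov.
gee_exchangeable <- function(formula, data, id, maxit = 25, tol = 1e-10) {
  mf <- stats::model.frame(formula, data = data)
  X <- stats::model.matrix(formula, mf)
  yv <- stats::model.response(mf)
  id <- as.character(id)
  if (length(id) != length(yv)) stop("id must match the model rows")
  cl <- split(seq_along(yv), id)
  p <- ncol(X)
  beta <- stats::coef(stats::lm.fit(X, yv))
  rho <- 0
  for (it in seq_len(maxit)) {
    res <- yv - X %*% beta
    phi <- sum(res^2) / (length(yv) - p)
    num <- 0; den <- 0
    for (ix in cl) {
      ni <- length(ix)
      if (ni < 2) next
      ri <- res[ix]
      num <- num + (sum(ri)^2 - sum(ri^2)) / 2
      den <- den + ni * (ni - 1) / 2
    }
    rho_new <- if (den > 0) max(-0.99, min(0.99, num / (den * phi))) else 0
    B <- matrix(0, p, p); u <- numeric(p)
    for (ix in cl) {
      ni <- length(ix)
      Ri_inv <- if (ni == 1) matrix(1, 1, 1) else {
        a <- 1 - rho_new
        (diag(ni) - matrix(rho_new / (a + ni * rho_new), ni, ni)) / a
      }
      Xi <- X[ix, , drop = FALSE]
      B <- B + crossprod(Xi, Ri_inv %*% Xi)
      u <- u + crossprod(Xi, Ri_inv %*% yv[ix])
    }
    beta_new <- solve(B, u)
    done <- max(abs(beta_new - beta)) < tol && abs(rho_new - rho) < tol
    beta <- beta_new; rho <- rho_new
    if (done) break
  }
  res <- yv - X %*% beta
  B <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in cl) {
    ni <- length(ix)
    Ri_inv <- if (ni == 1) matrix(1, 1, 1) else {
      a <- 1 - rho
      (diag(ni) - matrix(rho / (a + ni * rho), ni, ni)) / a
    }
    Xi <- X[ix, , drop = FALSE]
    XtR <- crossprod(Xi, Ri_inv)
    B <- B + XtR %*% Xi
    s <- XtR %*% res[ix]
    M <- M + s %*% t(s)
  }
  Binv <- solve(B)
  vcov <- Binv %*% M %*% Binv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       vcov = vcov, rho = rho, n_clusters = length(cl))
}

#' Body-weight contrast between gait classes over age
#'
#' Repeated body weights of the same birds across ages are analyzed with a
#' Gaussian marginal model (generalized estimating equations, exchangeable
#' working correlation on bird, robust sandwich errors): weight ~ age x gait
#' class. Reports the suboptimal-minus-good contrast at each age with a
#' robust 95% CI and two-sided P.
#'
#' @param meta Data frame with `bird_id`, `age_days`, `body_weight_g`,
#'   `gait_class` (repeated over ages per bird).
#' @param config An [analysis_config()].
#' @return Data frame with one row per age: `age_days`, `diff`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
bodyweight_class_contrast <- function(meta, config = analysis_config()) {
  meta$gait_class <- factor(meta$gait_class, levels = c("good", "suboptimal"))
  if (any(table(meta$gait_class[!duplicated(meta$bird_id)]) < 2))
    stop("class contrast inestimable: fewer than 2 birds in a class")
  meta$age_f <- factor(meta$age_days)
  form <- if (nlevels(meta$age_f) > 1) body_weight_g ~ age_f * gait_class
          else body_weight_g ~ gait_class
  fit <- gee_exchangeable(form, meta, id = meta$bird_id)
  ages <- levels(meta$age_f)
  cn <- names(fit$coefficients)
  out <- lapply(ages, function(a) {
    L <- stats::setNames(numeric(length(cn)), cn)
    L["gait_classsuboptimal"] <- 1
    inter <- paste0("age_f", a, ":gait_classsuboptimal")
    if (inter %in% cn) L[inter] <- 1
    est <- sum(L * fit$coefficients)
    se <- sqrt(drop(t(L) %*% fit$vcov %*% L))
    data.frame(age_days = as.integer(a), diff = est,
               ci_low = est - stats::qnorm(0.975) * se,
               ci_high = est + stats::qnorm(0.975) * se,
               p = 2 * stats::pnorm(-abs(est / se)))
  })
  do.call(rbind, out)
}

#' Label a P value
#'
#' `P <= alpha` is significant, `alpha < P <= tendency_upper` a tendency,
#' larger values not significant.
#'
#' @param p P value(s) in \[0, 1\].
#' @param config An [analysis_config()].
#' @return Character label(s).
#' @export
significance_label <- function(p, config = analysis_config()) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p <= config$alpha, "significant",
         ifelse(p <= config$tendency_upper, "tendency", "ns"))
}
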