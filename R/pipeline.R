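default_config <- function() {
  list(
    seed = 1L,
    simulate = list(n_good = 48L, n_suboptimal = 36L, n_nonwalkers = 0L,
                    ages = c(14, 21, 33), noise_sd_px = 4, dropout_prob = 0.05),
    clean = list(trim_fraction = 0.10, likelihood_threshold = 0.6,
                 smoothing = "none", smoothing_cap_sd = 4),
    poses = list(k = 3L, min_separation = 6L, prominence_sd = 3,
                 contact_tolerance = 0.10),
    analysis = list(iqr_multiplier = 2, alpha = 0.05, tendency_upper = 0.10,
                    cutoff = 2.0, analysis_age = 33L)
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML file path, a nested list, or `NULL` (all defaults). Fills
#' defaults for missing fields, rejects unknown keys (with a suggestion for
#' the nearest known key) and out-of-range values with messages naming the
#' offending field.
#'
#' @param config Path to a YAML file, a nested list, or `NULL`.
#' @return The normalized configuration list, with the per-stage
#'   configuration objects attached as attribute `stages`.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  def <- default_config()
  merged <- def
  check_keys <- function(given, known, where) {
    bad <- setdiff(names(given), known)
    if (length(bad)) {
      near <- vapply(bad, function(b) {
        hit <- known[utils::adist(b, known) <= 3]
        if (length(hit)) paste0(" (did you mean '", hit[1], "'?)") else ""
      }, "")
      stop("unknown config key", if (length(bad) > 1) "s", " in ", where, ": ",
           paste0("'", bad, "'", near, collapse = ", "))
    }
  }
  check_keys(config, names(def), "top level")
  for (blk in intersect(names(config), names(def))) {
    if (blk == "seed") { merged$seed <- as.integer(config$seed); next }
    check_keys(config[[blk]], names(def[[blk]]), paste0("block '", blk, "'"))
    merged[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  sim <- merged$simulate
  if (sim$n_good < 0 || sim$n_suboptimal < 0 || sim$n_nonwalkers < 0)
    stop("simulate: cohort sizes must be non-negative")
  stages <- list(
    clean = do.call(cleaning_config, merged$clean),
    poses = do.call(pose_config, merged$poses),
    analysis = do.call(analysis_config, merged$analysis)
  )
  attr(merged, "stages") <- stages
  merged
}

#' Clean one trial and extract its feature records
#'
#' Applies the full per-trial chain: clip to manual bounds, discard the first
#' and last trim fraction, mask low-likelihood frames, optionally smooth,
#' detect gait phases, select pose frames, and aggregate the features.
#'
#' @param trial A [tracked_trial()].
#' @param clean A [cleaning_config()].
#' @param poses A [pose_config()].
#' @return Feature records as from [aggregate_features()].
#' @export
extract_trial_features <- function(trial, clean = cleaning_config(),
                                   poses = pose_config()) {
  trial <- clip_trial(trial)
  trial <- trim_edges(trial, clean)
  trial <- mask_low_likelihood(trial, clean)
  trial <- smooth_trajectories(trial, clean)
  aggregate_features(extract_poses(trial, config = poses))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, cleans each trial, extracts poses and features,
#' screens outliers, classifies gait from the simulated rater scores, and
#' fits the full statistical layer: descriptive feature statistics by age,
#' class-difference models at the analysis age, feature correlations, rater
#' agreement, and the repeated-measures body-weight contrast. Birds whose
#' trials yield no usable pose are excluded and logged. Re-running with the
#' same seed reproduces every number.
#'
#' @param config Configuration (path, list or `NULL`); see
#'   [validate_config()].
#' @param out_dir Optional directory into which the result tables are
#'   written as CSV (plus a plain-text run log).
#' @return A list of class `gait_report`: `records`, `table1`, `table2`,
#'   `correlations`, `classes`, `kappa`, `bodyweight`,
#'   `likelihood_summary`, `exclusions`, `log`, `config`.
#' @export
run_pipeline <- function(config = NULL, out_dir = NULL) {
  cfg <- validate_config(config)
  st <- attr(cfg, "stages")
  sim <- cfg$simulate
  params <- lapply(sim$ages, function(a)
    gait_params(a, noise_sd_px = sim$noise_sd_px,
                dropout_prob = sim$dropout_prob))
  cohort <- simulate_cohort(sim$n_good, sim$n_suboptimal, ages = sim$ages,
                            seed = cfg$seed, params = params,
                            n_nonwalkers = sim$n_nonwalkers)
  res <- pipeline_analyze(cohort, st, cfg)
  if (!is.null(out_dir)) write_report(res, out_dir)
  res
}

# Analysis half of the pipeline: everything downstream of the simulated (or
# loaded) cohort.
pipeline_analyze <- function(cohort, st, cfg = NULL) {
  records <- list(); exclusions <- list()
  for (bid in names(cohort$trials)) {
    for (a in names(cohort$trials[[bid]])) {
      rec <- tryCatch(
        suppressWarnings(extract_trial_features(cohort$trials[[bid]][[a]],
                                                st$clean, st$poses)),
        error = function(e) conditionMessage(e))
      if (is.character(rec)) {
        exclusions[[length(exclusions) + 1]] <-
          data.frame(bird_id = bid, age_days = as.integer(a), reason = rec)
      } else {
        records[[length(records) + 1]] <- rec
      }
    }
  }
  records <- do.call(rbind, records)
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(bird_id = character(0), age_days = integer(0),
               reason = character(0))
  n_before <- nrow(records)
  records <- filter_outliers(records, st$analysis)

  mean_scores <- mean_gait_score(cohort$scores)
  classes <- data.frame(bird_id = rownames(cohort$scores),
                        mean_score = mean_scores,
                        gait_class = classify_gait(mean_scores,
                                                   st$analysis$cutoff),
                        row.names = NULL)
  # analyzed birds: walked at the analysis age
  aage <- st$analysis$analysis_age
  analyzed <- unique(records$bird_id[records$age_days == aage])
  meta <- merge(cohort$meta, classes[c("bird_id", "gait_class")], by = "bird_id")
  meta_a <- meta[meta$bird_id %in% analyzed, ]

  table1 <- stats::aggregate(value ~ feature + age_days, data = records,
                             FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                                 n = length(v)))
  table1 <- cbind(table1[1:2], as.data.frame(table1$value))
  table1 <- table1[order(match(table1$feature, feature_names()),
                         table1$age_days), ]

  sided <- c("hock_joint_angle", "shank_floor_angle",
             "tibiotarsus_rel_length", "shank_rel_length")
  ratios <- c("hock_knee_ratio", "hock_feet_ratio")
  table2 <- list()
  for (f in c(sided, "step_height_rel"))
    table2[[f]] <- try(feature_class_model(records, meta_a, f, st$analysis),
                       silent = TRUE)
  for (f in ratios)
    table2[[f]] <- try(ratio_class_model(records, meta_a, f, st$analysis),
                       silent = TRUE)
  table2 <- do.call(rbind, table2[!vapply(table2, inherits, TRUE, "try-error")])
  if (!is.null(table2)) {
    table2$label <- significance_label(table2$p, st$analysis)
    table2 <- table2[order(match(table2$feature, feature_names())), ]
    rownames(table2) <- NULL
  }

  corr <- feature_correlations(records, st$analysis)
  kappa <- list(fleiss = fleiss_kappa(cohort$scores),
                cohen = lapply(colnames(cohort$scores), function(r)
                  cohen_weighted_kappa(cohort$repeat_scores$pass1[, r],
                                       cohort$repeat_scores$pass2[, r])))
  names(kappa$cohen) <- colnames(cohort$scores)
  bw <- bodyweight_class_contrast(meta_a, st$analysis)
  bw$label <- significance_label(bw$p, st$analysis)
  liks <- likelihood_summary(unlist(cohort$trials, recursive = FALSE), st$clean)

  log <- c(
    sprintf("gaitpose %s; R %s", as.character(utils::packageVersion("gaitpose")),
            paste(R.version$major, R.version$minor, sep = ".")),
    sprintf("seed: %d", cohort$seed),
    sprintf("birds simulated: %d", length(cohort$birds)),
    sprintf("bird-age trials: %d", nrow(cohort$meta)),
    sprintf("trials excluded (no usable pose): %d", nrow(exclusions)),
    sprintf("feature records before outlier screen: %d", n_before),
    sprintf("outlier records removed: %d", attr(records, "n_removed")),
    sprintf("birds analyzed at d%d: %d (good %d, suboptimal %d)",
            aage, nrow(meta_a[!duplicated(meta_a$bird_id), ]),
            sum(meta_a$gait_class[!duplicated(meta_a$bird_id)] == "good"),
            sum(meta_a$gait_class[!duplicated(meta_a$bird_id)] == "suboptimal")))

  structure(list(records = records, table1 = table1, table2 = table2,
                 correlations = corr, classes = classes, kappa = kappa,
                 bodyweight = bw, likelihood_summary = liks,
                 exclusions = exclusions, log = log, config = cfg),
            class = "gait_report")
}

#' @export
print.gait_report <- function(x, ...) {
  cat("<gait_report>\n")
  cat(paste0("  ", x$log, "\n"), sep = "")
  if (!is.null(x$table2)) {
    cat("  class differences at analysis age:\n")
    print(cbind(x$table2[c("feature")],
                round(x$table2[c("value_at_good", "diff", "ci_low", "ci_high",
                                 "p", "pct_diff")], 3),
                label = x$table2$label))
  }
  invisible(x)
}

write_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                           row.names = FALSE)
  w(res$records, "feature_records.csv")
  w(res$table1, "features_by_age.csv")
  if (!is.null(res$table2)) w(res$table2, "class_differences.csv")
  w(res$classes, "gait_classes.csv")
  w(res$bodyweight, "bodyweight_contrast.csv")
  w(res$likelihood_summary, "likelihood_summary.csv")
  w(res$exclusions, "exclusions.csv")
  kap <- data.frame(
    statistic = c("fleiss", paste0("cohen_", names(res$kappa$cohen))),
    kappa = c(res$kappa$fleiss$kappa,
              vapply(res$kappa$cohen, `[[`, 0, "kappa")),
    band = c(res$kappa$fleiss$band,
             vapply(res$kappa$cohen, `[[`, "", "band")))
  w(kap, "kappa.csv")
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
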