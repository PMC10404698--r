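# Shared fixtures, all built in code.

# Minimal trial: constant coordinates, full likelihood, n frames.
flat_trial <- function(n = 20, lik = 1, age = 33L) {
  x <- matrix(rep(seq(100, 800, length.out = 8), each = n), n, 8,
              dimnames = list(NULL, body_parts()))
  y <- matrix(rep(c(100, 150, 470, 470, 560, 560, 620, 620), each = n), n, 8,
              dimnames = list(NULL, body_parts()))
  l <- matrix(lik, n, 8, dimnames = list(NULL, body_parts()))
  tracked_trial(x, y, l, bird_id = "flat", age_days = age,
                start_frame = 0L, end_frame = n - 1L)
}

# A hand-built double-support pose; defaults match the worked geometry used
# throughout the feature tests (right leg: knee (100,200) hock (110,260)
# foot (105,330) mirrored on the left around x = 0).
make_pose <- function(kind = "double_support",
                      coords = NULL, frame = 0L) {
  if (is.null(coords)) {
    coords <- rbind(
      knee_left  = c(-100, 200), knee_right = c(100, 200),
      hock_left  = c(-110, 260), hock_right = c(110, 260),
      foot_left  = c(-105, 330), foot_right = c(105, 330))
    colnames(coords) <- c("x", "y")
  }
  structure(list(frame = frame, kind = kind,
                 coords = coords[leg_parts(), ]), class = "pose")
}

# Parameters for the deterministic (noise-free) limit of the simulator;
# explicit overrides win over the noise-free settings.
noiseless_params <- function(age = 33, ...) {
  args <- list(noise_sd_px = 0, dropout_prob = 0, knee_bias_sd_px = 0,
               ground_asym_sd_px = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(gait_params, c(list(age_days = age), args))
}

# One noiseless simulated bird + trial at one age.
noiseless_trial <- function(seed = 7, age = 33, n_good = 1, n_sub = 0, ...) {
  p <- stats::setNames(list(noiseless_params(age, ...)), as.character(age))
  simulate_cohort(n_good, n_sub, ages = age, seed = seed, params = p)
}

default_stages <- function() {
  list(clean = cleaning_config(), poses = pose_config(),
       analysis = analysis_config())
}

# Exhaustive subset-selection oracle: all candidate subsets of size <= k with
# pairwise separation >= sep; maximize count, then optimize total value.
brute_force_select <- function(frames, values, k, sep, minimize = FALSE) {
  m <- length(frames)
  best <- list(count = 0L, total = if (minimize) Inf else -Inf, sel = integer(0))
  for (size in seq_len(min(k, m))) {
    idx <- utils::combn(m, size)
    for (j in seq_len(ncol(idx))) {
      s <- idx[, j]
      f <- frames[s]
      if (size > 1 && min(diff(sort(f))) < sep) next
      tot <- sum(values[s])
      better <- size > best$count ||
        (size == best$count &&
           ((minimize && tot < best$total - 1e-12) ||
              (!minimize && tot > best$total + 1e-12)))
      if (better) best <- list(count = size, total = tot, sel = sort(f))
    }
  }
  best
}
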