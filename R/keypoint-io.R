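#' Read a DeepLabCut-dialect keypoint table
#'
#' Parses the CSV layout exported by DeepLabCut: three header rows (scorer,
#' bodyparts, coords), a first column holding the integer frame index, and for
#' each body part the columns x, y, likelihood in that fixed order. Files with
#' any other coords variant are rejected rather than guessed. Missing cells
#' become `NA` coordinates with likelihood 0.
#'
#' @param path Path to the CSV file.
#' @param bird_id,age_days,fps,frame_size,start_frame,end_frame Trial metadata
#'   passed to [tracked_trial()] (the DLC format itself carries none).
#' @return A [tracked_trial()].
#' @export
read_keypoint_table <- function(path, bird_id = "bird", age_days = 33L,
                                fps = 12, frame_size = c(1280L, 720L),
                                start_frame = NA, end_frame = NA) {
  lines <- readLines(path)
  if (length(lines) < 3)
    stop("malformed keypoint table: fewer than 3 header rows in ", path)
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  labels <- vapply(hdr, `[`, "", 1L)
  if (!identical(tolower(labels), c("scorer", "bodyparts", "coords"))) {
    bad <- which(tolower(labels) != c("scorer", "bodyparts", "coords"))[1]
    stop(sprintf(
      "malformed keypoint table header: row %d starts with '%s', expected '%s'",
      bad, labels[bad], c("scorer", "bodyparts", "coords")[bad]))
  }
  parts_row <- hdr[[2]][-1]
  coords_row <- hdr[[3]][-1]
  if (length(parts_row) %% 3 != 0 ||
      !identical(unname(coords_row),
                 rep(c("x", "y", "likelihood"), length(parts_row) / 3)))
    stop("malformed keypoint table: coords row must repeat x, y, likelihood per part")
  parts <- parts_row[seq(1, length(parts_row), by = 3)]
  if (!identical(sort(parts), sort(body_parts())))
    stop("unknown body-part labels: ",
         paste(setdiff(parts, body_parts()), collapse = ", "),
         "; expected: ", paste(body_parts(), collapse = ", "))
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  nf <- length(body)
  x <- y <- lik <- matrix(NA_real_, nf, 8,
                          dimnames = list(NULL, parts))
  if (nf > 0) {
    dat <- utils::read.csv(text = body, header = FALSE)
    if (ncol(dat) != 1 + 3 * length(parts))
      stop("malformed keypoint table: wrong number of data columns")
    for (j in seq_along(parts)) {
      x[, j] <- as.numeric(dat[[1 + 3 * (j - 1) + 1]])
      y[, j] <- as.numeric(dat[[1 + 3 * (j - 1) + 2]])
      lik[, j] <- as.numeric(dat[[1 + 3 * (j - 1) + 3]])
    }
    lik[is.na(lik)] <- 0
  }
  tracked_trial(x[, body_parts(), drop = FALSE],
                y[, body_parts(), drop = FALSE],
                lik[, body_parts(), drop = FALSE],
                bird_id = bird_id, age_days = age_days, fps = fps,
                frame_size = frame_size,
                start_frame = start_frame, end_frame = end_frame)
}

#' Write a trial as a DeepLabCut-dialect keypoint table
#'
#' Emits the same three-header-row CSV dialect read by
#' [read_keypoint_table()]; reading a written file recovers the trial up to
#' float text precision. Likelihood-0 cells are serialized, not dropped.
#'
#' @param trial A [tracked_trial()].
#' @param path Output CSV path.
#' @param scorer Scorer label placed in the first header row.
#' @return Invisibly, `path`.
#' @export
write_keypoint_table <- function(trial, path, scorer = "gaitpose") {
  validate_trial(trial)
  parts <- body_parts()
  hdr1 <- paste(c("scorer", rep(scorer, 24)), collapse = ",")
  hdr2 <- paste(c("bodyparts", rep(parts, each = 3)), collapse = ",")
  hdr3 <- paste(c("coords", rep(c("x", "y", "likelihood"), 8)), collapse = ",")
  n <- n_frames(trial)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open ", path, " for writing")
  on.exit(close(con))
  writeLines(c(hdr1, hdr2, hdr3), con)
  if (n > 0) {
    cols <- vector("list", 1 + 24)
    cols[[1]] <- trial$frames
    for (j in seq_along(parts)) {
      cols[[1 + 3 * (j - 1) + 1]] <- trial$x[, parts[j]]
      cols[[1 + 3 * (j - 1) + 2]] <- trial$y[, parts[j]]
      cols[[1 + 3 * (j - 1) + 3]] <- trial$likelihood[, parts[j]]
    }
    dat <- do.call(data.frame, stats::setNames(cols, paste0("c", seq_along(cols))))
    utils::write.table(format(dat, digits = 17, trim = TRUE, scientific = FALSE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read or write cohort metadata
#'
#' Cohort metadata is a flat CSV with one row per bird-age: `bird_id`,
#' `age_days`, `body_weight_g`, `group`. Body weights must be positive and
#' unique per bird-age.
#'
#' @param path CSV path.
#' @return `read_cohort_meta()`: a data frame; `write_cohort_meta()`: `path`,
#'   invisibly.
#' @export
read_cohort_meta <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("bird_id", "age_days", "body_weight_g")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("cohort metadata lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(meta$body_weight_g <= 0)) stop("body weights must be positive")
  if (anyDuplicated(meta[c("bird_id", "age_days")]))
    stop("one body weight per bird-age expected")
  meta
}

#' @rdname read_cohort_meta
#' @param meta Data frame as returned by [read_cohort_meta()].
#' @export
write_cohort_meta <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
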