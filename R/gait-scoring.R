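#' Mean gait score of a bird
#'
#' Each bird is assigned the arithmetic mean of the independent 0-5 gait
#' scores given by its raters.
#'
#' @param scores A birds x raters matrix (or data frame) of integer scores
#'   0-5, with bird ids as row names, or a numeric vector for a single bird.
#' @param bird Optional bird id (row) to extract.
#' @return Mean score(s).
#' @export
mean_gait_score <- function(scores, bird = NULL) {
  if (is.vector(scores)) return(mean(check_scores(scores)))
  scores <- as.matrix(scores)
  check_scores(scores)
  if (!is.null(bird)) {
    if (!bird %in% rownames(scores)) stop("no scores recorded for bird ", bird)
    return(mean(scores[bird, ], na.rm = TRUE))
  }
  rowMeans(scores, na.rm = TRUE)
}

check_scores <- function(s) {
  v <- s[!is.na(s)]
  if (length(v) == 0) stop("no scores available")
  if (any(v < 0 | v > 5 | v != round(v)))
    stop("gait scores must be integers in 0..5")
  s
}

#' Classify gait from the mean score
#'
#' Birds at or below the cutoff have good gait; above it, suboptimal gait.
#' The default cutoff of 2 reflects the assumption that gait scores above 2
#' potentially impair welfare; 2.5 and 3 are the usual robustness cutoffs.
#'
#' @param mean_score Numeric mean gait score(s).
#' @param cutoff Classification cutoff (default 2).
#' @return Factor with levels `good`, `suboptimal`.
#' @export
classify_gait <- function(mean_score, cutoff = 2.0) {
  factor(ifelse(mean_score <= cutoff, "good", "suboptimal"),
         levels = c("good", "suboptimal"))
}

#' Fleiss' kappa for multi-rater agreement
#'
#' Chance-corrected agreement of several raters assigning categorical scores
#' (here the 0-5 gait scale) to the same subjects:
#' kappa = (Pbar - Pe) / (1 - Pe), with Pbar the mean per-subject pairwise
#' agreement and Pe the expectation from the category marginals. If every
#' rating falls in one category, Pe = 1 and kappa is undefined.
#'
#' @param scores Complete birds x raters matrix of integer scores 0-5.
#' @param categories Vector of admissible categories (default 0:5).
#' @return A list of class `kappa_result` with `kappa`, `band` and `n`.
#' @export
fleiss_kappa <- function(scores, categories = 0:5) {
  scores <- as.matrix(scores)
  check_scores(scores)
  if (anyNA(scores)) stop("fleiss_kappa needs a complete table")
  n <- nrow(scores); r <- ncol(scores)
  if (r < 2) stop("at least 2 raters required")
  counts <- t(apply(scores, 1, function(row)
    tabulate(match(row, categories), nbins = length(categories))))
  p_j <- colSums(counts) / (n * r)
  P_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (1 - Pe < .Machine$double.eps^0.5) {
    return(structure(list(kappa = NA_real_, band = NA_character_, n = n,
                          undefined = TRUE),
                     class = "kappa_result"))
  }
  k <- (Pbar - Pe) / (1 - Pe)
  structure(list(kappa = k, band = agreement_band(k), n = n,
                 undefined = FALSE),
            class = "kappa_result")
}

#' Cohen's weighted kappa for paired ratings
#'
#' Agreement between two rating passes on the same subjects, with
#' disagreements discounted by their distance on the ordinal scale:
#' weights w_ij = 1 - (|i - j| / (C - 1))^p with p = 1 (linear, default) or
#' p = 2 (quadratic).
#'
#' @param pass1,pass2 Integer score vectors (0-5) of the same birds.
#' @param weighting `"linear"` or `"quadratic"`.
#' @param categories Vector of admissible categories (default 0:5).
#' @return A list of class `kappa_result`.
#' @export
cohen_weighted_kappa <- function(pass1, pass2,
                                 weighting = c("linear", "quadratic"),
                                 categories = 0:5) {
  weighting <- match.arg(weighting)
  check_scores(pass1); check_scores(pass2)
  if (length(pass1) != length(pass2)) stop("passes must rate the same birds")
  if (length(pass1) < 2) stop("at least 2 paired ratings required")
  p <- if (weighting == "linear") 1 else 2
  C <- length(categories)
  w <- 1 - (abs(outer(categories, categories, "-")) / (C - 1))^p
  i1 <- factor(pass1, levels = categories)
  i2 <- factor(pass2, levels = categories)
  obs <- table(i1, i2) / length(pass1)
  exp_ <- outer(rowSums(obs), colSums(obs))
  po <- sum(w * obs)
  pe <- sum(w * exp_)
  if (1 - pe < .Machine$double.eps^0.5) {
    return(structure(list(kappa = NA_real_, band = NA_character_,
                          n = length(pass1), undefined = TRUE),
                     class = "kappa_result"))
  }
  k <- (po - pe) / (1 - pe)
  structure(list(kappa = k, band = agreement_band(k), n = length(pass1),
                 undefined = FALSE, weighting = weighting),
            class = "kappa_result")
}

#' Landis-Koch agreement band of a kappa value
#'
#' Maps kappa to the conventional verbal bands: below 0 poor, 0 to 0.20
#' slight, 0.21 to 0.40 fair, 0.41 to 0.60 moderate, 0.61 to 0.80 good,
#' 0.81 to 1.00 excellent. Printed range endpoints are upper-inclusive
#' (0.20 is slight, 0.205 is fair).
#'
#' @param kappa Numeric kappa in \[-1, 1\].
#' @return Character band label.
#' @export
agreement_band <- function(kappa) {
  stopifnot(kappa >= -1, kappa <= 1)
  if (kappa < 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "good"
  else "excellent"
}

#' @export
print.kappa_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat("<kappa_result> undefined (no chance-corrected variation)\n")
  } else {
    cat(sprintf("<kappa_result> kappa = %.3f (%s agreement), n = %d%s\n",
                x$kappa, x$band, x$n,
                if (!is.null(x$weighting)) paste0(", ", x$weighting, " weights")
                else ""))
  }
  invisible(x)
}
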