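# FNGS 2.0 bookkeeping and EAR-difference -> eye-score classification.
#
# The Facial Nerve Grading Scale 2.0 scores four facial regions (brow,
# eye, nasolabial fold, oral) from 1 (normal) to 6 (no movement) plus a
# 0-3 secondary-movement (synkinesis/contracture) score; the total maps to
# grades I-VI. This module holds the scale arithmetic, cohort exclusion
# bookkeeping, per-score summaries, and a scalar classifier that predicts
# the eye score from the bilateral EAR difference.

#' FNGS 2.0 grade from a total score
#'
#' Band lookup: I = 4, II = 5-9, III = 10-14, IV = 15-19, V = 20-23,
#' VI = 24. Totals above 24 (possible when the secondary-movement score
#' pushes past the band table, max 4 x 6 + 3 = 27) clamp to VI.
#'
#' @param total integer total score(s), each >= 4.
#' @return character vector of grades `"I"` .. `"VI"`.
#' @export
grade_from_total <- function(total) {
  if (!is.numeric(total) || anyNA(total) || any(total != round(total)))
    stop("total must be whole numbers")
  if (any(total < 4)) stop("FNGS 2.0 total cannot be below 4")
  if (any(total > 27)) stop("FNGS 2.0 total cannot exceed 27")
  cut(total, breaks = c(3, 4, 9, 14, 19, 23, 27),
      labels = c("I", "II", "III", "IV", "V", "VI")) |> as.character()
}

#' Construct an FNGS 2.0 record
#'
#' @param brow,eye,nlf,oral per-region scores, integers 1-6 (nlf =
#'   nasolabial fold).
#' @param secondary_movement global synkinesis/contracture score, 0-3.
#' @return list of class `fngs_record` with the regional scores, `total`
#'   and `grade`.
#' @export
fngs_record <- function(brow, eye, nlf, oral, secondary_movement = 0L) {
  reg <- c(brow = brow, eye = eye, nlf = nlf, oral = oral)
  if (any(reg < 1 | reg > 6 | reg != round(reg)))
    stop("regional scores must be integers in 1..6")
  if (secondary_movement < 0 || secondary_movement > 3 ||
      secondary_movement != round(secondary_movement))
    stop("secondary_movement must be an integer in 0..3")
  total <- sum(reg) + secondary_movement
  structure(list(brow = as.integer(brow), eye = as.integer(eye),
                 nlf = as.integer(nlf), oral = as.integer(oral),
                 secondary_movement = as.integer(secondary_movement),
                 total = as.integer(total), grade = grade_from_total(total)),
            class = "fngs_record")
}

#' @export
print.fngs_record <- function(x, ...) {
  cat(sprintf(
    "FNGS 2.0: brow %d, eye %d, NLF %d, oral %d, secondary %d -> total %d, grade %s\n",
    x$brow, x$eye, x$nlf, x$oral, x$secondary_movement, x$total, x$grade))
  invisible(x)
}

#' Assemble a cohort table
#'
#' @param subject_id character vector.
#' @param ear_difference non-negative bilateral EAR differences.
#' @param fngs_eye_score integer eye scores 1-6.
#' @return data frame with columns `subject_id`, `ear_difference`,
#'   `fngs_eye_score`, `excluded` (logical), `reason` (character).
#' @export
cohort_table <- function(subject_id, ear_difference, fngs_eye_score) {
  n <- length(subject_id)
  stopifnot(length(ear_difference) == n, length(fngs_eye_score) == n)
  if (any(ear_difference < 0)) stop("ear_difference must be non-negative")
  if (any(!fngs_eye_score %in% 1:6))
    stop("fngs_eye_score must be integers in 1..6")
  data.frame(subject_id = as.character(subject_id),
             ear_difference = as.numeric(ear_difference),
             fngs_eye_score = as.integer(fngs_eye_score),
             excluded = FALSE, reason = "",
             stringsAsFactors = FALSE)
}

#' Mark incorrectly detected samples as excluded
#'
#' Samples whose landmark detections fail quality control (see
#' [flag_incorrect_detection()]) are excluded from the correlation and
#' classification analyses, mirroring standard cohort curation. Counts are
#' conserved: per score, original = retained + excluded.
#'
#' @param cohort data frame from [cohort_table()].
#' @param flags logical vector aligned with `cohort` rows; `TRUE` excludes.
#' @param reason reason string recorded on excluded rows.
#' @return list with `cohort` (flags applied) and `report`, a data frame
#'   per score with columns `score`, `original`, `retained`, `excluded`.
#' @export
apply_exclusions <- function(cohort, flags,
                             reason = "incorrect landmark detection") {
  stopifnot(is.data.frame(cohort))
  if (length(flags) != nrow(cohort))
    stop("flags length (", length(flags), ") != cohort rows (",
         nrow(cohort), ")")
  flags <- as.logical(flags)
  cohort$excluded <- cohort$excluded | flags
  cohort$reason[flags] <- reason
  if (any(cohort$excluded & !nzchar(cohort$reason)))
    stop("excluded samples must carry a reason")
  per_score <- function(score) {
    rows <- cohort$fngs_eye_score == score
    c(original = sum(rows), retained = sum(rows & !cohort$excluded),
      excluded = sum(rows & cohort$excluded))
  }
  counts <- t(vapply(1:6, per_score, numeric(3)))
  report <- data.frame(score = 1:6, counts)
  list(cohort = cohort, report = report)
}

retained <- function(cohort) cohort[!cohort$excluded, , drop = FALSE]

#' Median bilateral EAR difference per eye score
#'
#' @param cohort data frame from [cohort_table()]; excluded rows are
#'   ignored.
#' @return named numeric vector over scores 1-6; `NA` for empty classes.
#' @export
median_by_score <- function(cohort) {
  keep <- retained(cohort)
  vapply(1:6, function(s) {
    v <- keep$ear_difference[keep$fngs_eye_score == s]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1)) |> stats::setNames(as.character(1:6))
}

#' Correlation between EAR difference and eye score
#'
#' @inheritParams median_by_score
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation coefficient over the non-excluded samples.
#' @export
score_correlation <- function(cohort, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- retained(cohort)
  if (nrow(keep) < 3L || length(unique(keep$fngs_eye_score)) < 2L)
    stop("need >= 3 retained samples spanning >= 2 scores")
  if (stats::sd(keep$ear_difference) == 0)
    stop("correlation undefined: ear_difference has zero variance")
  stats::cor(keep$ear_difference, keep$fngs_eye_score, method = method)
}

#' Fit an eye-score classifier on the scalar EAR-difference feature
#'
#' The per-score distributions of the bilateral EAR difference are well
#' separated, so a very small model suffices. The default assigns a new
#' sample the score whose training-class median is nearest (ties to the
#' lower score). `"thresholds"` instead cuts the feature axis at the
#' midpoints between consecutive sorted class medians; `"knn3"` is a
#' 3-nearest-neighbour majority vote (ties to the lower score).
#'
#' @param ear_difference numeric training feature values.
#' @param score integer training eye scores 1-6, aligned.
#' @param method `"nearest_median"`, `"thresholds"` or `"knn3"`.
#' @return object of class `ear_score_classifier` with a [predict][
#'   predict.ear_score_classifier] method.
#' @export
fit_eye_score_classifier <- function(ear_difference, score,
                                     method = c("nearest_median",
                                                "thresholds", "knn3")) {
  method <- match.arg(method)
  if (length(ear_difference) == 0L) stop("empty training set")
  stopifnot(length(score) == length(ear_difference))
  if (any(!score %in% 1:6)) stop("scores must be integers in 1..6")
  scores_seen <- sort(unique(as.integer(score)))
  medians <- vapply(scores_seen, function(s)
    stats::median(ear_difference[score == s]), numeric(1))
  structure(list(method = method, class_medians = medians,
                 classes = scores_seen,
                 train_x = as.numeric(ear_difference),
                 train_y = as.integer(score)),
            class = "ear_score_classifier")
}

#' Predict eye scores from bilateral EAR differences
#'
#' @param object an `ear_score_classifier`.
#' @param newdata numeric vector of EAR differences.
#' @param ... unused.
#' @return integer vector of predicted scores.
#' @export
predict.ear_score_classifier <- function(object, newdata, ...) {
  x <- as.numeric(newdata)
  switch(object$method,
    nearest_median = vapply(x, function(v) {
      gaps <- abs(object$class_medians - v)
      object$classes[which.min(gaps)]  # which.min takes the first = lowest score
    }, integer(1)),
    thresholds = {
      ord <- order(object$class_medians)
      med <- object$class_medians[ord]; cls <- object$classes[ord]
      cuts <- (head(med, -1) + tail(med, -1)) / 2
      # findInterval puts a value equal to a cut in the upper bin; nudge so
      # the tie goes to the lower score, matching nearest_median
      idx <- findInterval(x, cuts, left.open = TRUE) + 1L
      cls[idx]
    },
    knn3 = vapply(x, function(v) {
      nn <- order(abs(object$train_x - v), object$train_y)[
        seq_len(min(3L, length(object$train_x)))]
      tab <- table(object$train_y[nn])
      as.integer(names(tab)[which.max(tab)])
    }, integer(1)))
}

#' @export
print.ear_score_classifier <- function(x, ...) {
  cat("EAR-difference eye-score classifier (", x$method, ")\n", sep = "")
  cat("  class medians:\n")
  print(stats::setNames(x$class_medians, x$classes))
  invisible(x)
}

#' k-fold cross-validation of eye-score classification
#'
#' Randomly partitions the retained cohort into k folds (fold sizes differ
#' by at most 1), fits the classifier on k-1 folds and measures exact
#' 6-class score accuracy on the held-out fold.
#'
#' @inheritParams median_by_score
#' @param k number of folds (default 10).
#' @param seed RNG seed for the partition.
#' @param method classifier method, see [fit_eye_score_classifier()].
#' @param stratified balance score classes across folds (default `FALSE`:
#'   plain random partition).
#' @return list with `mean_accuracy`, `fold_accuracy` (length k), and
#'   `folds` (the fold assignment of each retained row).
#' @export
cross_validate <- function(cohort, k = 10L, seed = 1L,
                           method = "nearest_median", stratified = FALSE) {
  keep <- retained(cohort)
  n <- nrow(keep)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k (", k, ") exceeds cohort size (", n, ")")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (stratified) {
    folds <- integer(n)
    for (s in unique(keep$fngs_eye_score)) {
      rows <- which(keep$fngs_eye_score == s)
      folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
    }
  } else {
    folds <- sample(rep_len(seq_len(k), n))
  }
  fold_acc <- vapply(seq_len(k), function(f) {
    test <- folds == f
    fit <- fit_eye_score_classifier(keep$ear_difference[!test],
                                    keep$fngs_eye_score[!test],
                                    method = method)
    pred <- predict(fit, keep$ear_difference[test])
    mean(pred == keep$fngs_eye_score[test])
  }, numeric(1))
  list(mean_accuracy = mean(fold_acc), fold_accuracy = fold_acc,
       folds = folds)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
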