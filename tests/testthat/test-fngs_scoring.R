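test_that("grade bands map totals to grades I-VI", {
  expect_identical(grade_from_total(4), "I")
  expect_identical(grade_from_total(12), "III")
  expect_identical(grade_from_total(24), "VI")
  # total, monotone step function over the whole domain
  g <- grade_from_total(4:27)
  expect_identical(g[1:21],
                   c("I", rep("II", 5), rep("III", 5), rep("IV", 5),
                     rep("V", 4), "VI"))
  expect_identical(unique(g[21:24]), "VI")  # clamp above 24
  expect_true(all(diff(match(g, c("I", "II", "III", "IV", "V", "VI"))) >= 0))
  expect_error(grade_from_total(3), "below 4")
  expect_error(grade_from_total(4.5), "whole")
})

test_that("fngs_record totals regions plus secondary movement", {
  r <- fngs_record(brow = 2, eye = 3, nlf = 2, oral = 3,
                   secondary_movement = 1)
  expect_identical(r$total, 11L)
  expect_identical(r$grade, "III")
  expect_error(fngs_record(0, 1, 1, 1), "1\\.\\.6")
  expect_error(fngs_record(1, 1, 1, 1, secondary_movement = 4), "0\\.\\.3")
})

test_that("exclusion bookkeeping conserves per-score counts", {
  # per-score cohort sizes and exclusion counts of a 105-sample study
  # curated down to 87
  original <- c(5, 21, 31, 13, 23, 12)
  experimental <- c(5, 18, 25, 11, 18, 10)
  score <- rep(1:6, original)
  flags <- unlist(lapply(1:6, function(s)
    rep(c(TRUE, FALSE), c(original[s] - experimental[s], experimental[s]))))
  cohort <- cohort_table(sprintf("s%03d", seq_along(score)),
                         ear_difference = seq_along(score) / 100,
                         fngs_eye_score = score)
  res <- apply_exclusions(cohort, flags)
  expect_identical(res$report$original, as.numeric(original))
  expect_identical(res$report$retained, as.numeric(experimental))
  expect_identical(res$report$excluded,
                   as.numeric(original - experimental))
  expect_identical(sum(res$report$excluded), 18)
  # conservation: original = retained + excluded, per score
  expect_identical(res$report$original,
                   res$report$retained + res$report$excluded)
  expect_true(all(nzchar(res$cohort$reason[res$cohort$excluded])))
  expect_error(apply_exclusions(cohort, flags[-1]), "length")
  # no flags: cohort unchanged
  res0 <- apply_exclusions(cohort, rep(FALSE, nrow(cohort)))
  expect_identical(res0$cohort$excluded, rep(FALSE, nrow(cohort)))
  # all flagged: nothing retained
  res1 <- apply_exclusions(cohort, rep(TRUE, nrow(cohort)))
  expect_identical(sum(res1$report$retained), 0)
})

test_that("median_by_score summarises retained samples only", {
  cohort <- cohort_table(letters[1:7],
                         c(0.1, 0.2, 0.3, 1, 2, 3, 9),
                         c(1, 1, 1, 2, 2, 2, 2))
  m <- median_by_score(cohort)
  expect_equal(unname(m[1:2]), c(0.2, 2.5))
  expect_true(all(is.na(m[3:6])))  # empty classes absent, not an error
  cohort$excluded[7] <- TRUE; cohort$reason[7] <- "qc"
  expect_equal(unname(median_by_score(cohort)[2]), 2)  # median of {1,2,3}
})

test_that("score correlation matches a hand-rolled Pearson oracle", {
  med <- c(0.0071, 0.0240, 0.0620, 0.1186, 0.1746, 0.2404)
  cohort <- cohort_table(letters[1:6], med, 1:6)
  # independent sum-formula Pearson on the six pairs
  x <- med; y <- 1:6; n <- 6
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(score_correlation(cohort), r_oracle, tolerance = 1e-12)
  # perfectly linear relation
  lin <- cohort_table(letters[1:6], (1:6) * 0.04, 1:6)
  expect_equal(score_correlation(lin), 1)
  # antisymmetry under negation of the feature
  neg <- cohort_table(letters[1:6], max(med) - med, 1:6)
  expect_equal(score_correlation(neg), -r_oracle, tolerance = 1e-12)
  expect_error(score_correlation(cohort_table("a", 0.1, 2)), ">= 3")
  const <- cohort_table(letters[1:4], rep(0.2, 4), c(1, 2, 3, 4))
  expect_error(score_correlation(const), "variance")
})

test_that("nearest-median classifier predicts with ties to the lower score", {
  fit <- fit_eye_score_classifier(c(0, 1), c(1L, 6L))
  expect_identical(predict(fit, 0.1), 1L)
  expect_identical(predict(fit, 0.9), 6L)
  expect_identical(predict(fit, 0.5), 1L)  # equidistant: lower score
  expect_error(fit_eye_score_classifier(numeric(0), integer(0)), "empty")
  # threshold variant agrees with nearest-median on separated classes
  set.seed(21)
  x <- c(rnorm(20, 0, 0.01), rnorm(20, 1, 0.01), rnorm(20, 2, 0.01))
  y <- rep(c(1L, 3L, 5L), each = 20)
  f1 <- fit_eye_score_classifier(x, y)
  f2 <- fit_eye_score_classifier(x, y, method = "thresholds")
  probe <- seq(-0.3, 2.3, by = 0.07)
  expect_identical(predict(f1, probe), predict(f2, probe))
})

test_that("cross-validation partitions evenly and scores sanely", {
  set.seed(5)
  cohort <- cohort_table(sprintf("s%02d", 1:87),
                         rep(c(0.01, 0.05, 0.1, 0.2, 0.3, 0.4),
                             length.out = 87) + runif(87, 0, 0.004),
                         rep(1:6, length.out = 87))
  cv <- cross_validate(cohort, k = 10, seed = 3)
  expect_length(cv$fold_accuracy, 10)
  expect_lte(diff(range(table(cv$folds))), 1)
  expect_gt(cv$mean_accuracy, 0.9)  # near-separable classes
  # memorizing a single-class cohort is perfect
  mono <- cohort_table(letters[1:8], runif(8), rep(3L, 8))
  expect_equal(cross_validate(mono, k = 4, seed = 1)$mean_accuracy, 1)
  # constant feature degenerates to always predicting one class:
  # accuracy ~ 1/6 on a balanced 6-class cohort
  flat <- cohort_table(sprintf("f%02d", 1:60), rep(0.2, 60),
                       rep(1:6, each = 10))
  acc <- cross_validate(flat, k = 10, seed = 2)$mean_accuracy
  expect_lt(abs(acc - 1 / 6), 0.1)
  expect_error(cross_validate(mono, k = 20), "exceeds")
  # stratified folds spread every class across folds
  cvs <- cross_validate(cohort, k = 10, seed = 3, stratified = TRUE)
  expect_length(cvs$fold_accuracy, 10)
})

test_that("cross-validation is reproducible from its seed", {
  cohort <- cohort_table(sprintf("s%02d", 1:30), runif(30),
                         rep(1:6, each = 5))
  a <- cross_validate(cohort, k = 5, seed = 11)
  b <- cross_validate(cohort, k = 5, seed = 11)
  expect_identical(a, b)
})
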