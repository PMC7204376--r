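test_that("template face is mirror-symmetric with open eyes", {
  tf <- template_face()
  expect_equal(ear_one_eye(tf, "left"), ear_one_eye(tf, "right"))
  expect_gt(interocular_distance(tf), 0)
  # midline through nasal root and nose tip
  expect_equal(lm_pt(tf, 27)[1], 100)
  expect_equal(lm_pt(tf, 33)[1], 100)
  # exact bilateral mirror of the eye contours
  left <- lm_pt(tf, 36:41)
  right <- lm_pt(tf, c(45, 44, 43, 42, 47, 46))
  expect_equal(200 - left[, 1], right[, 1], ignore_attr = TRUE)
  expect_equal(left[, 2], right[, 2], ignore_attr = TRUE)
})

test_that("patient configuration validates its physiology", {
  expect_error(patient_config(grade = 0), "1\\.\\.6")
  expect_error(patient_config(grade = 2, closure_amplitude = 0), "closure")
  bad_map <- default_residual_fractions()
  bad_map["3"] <- 0.9  # larger than grade 2: not non-increasing
  expect_error(patient_config(grade = 2, residual_fraction_map = bad_map),
               "non-increasing")
  expect_error(patient_config(grade = 2, jitter_px = -1), "jitter")
})

test_that("simulated patients follow the residual-fraction model", {
  # grade 1, noise-free: perfectly symmetric motion
  g1 <- simulate_patient(patient_config(grade = 1, jitter_px = 0,
                                        head_sway_deg = 0, seed = 8))
  expect_lt(bilateral_ear_difference(g1$sequence), 1e-9)
  # grade 6: affected side never moves
  g6 <- simulate_patient(patient_config(grade = 6, jitter_px = 0,
                                        head_sway_deg = 0, seed = 8))
  aff <- ear_curves(g6$sequence)$left  # affected_side defaults to left
  expect_lt(diff(range(aff)), 1e-9)
  # healthy side reaches (near-)closure mid-cycle
  heal <- ear_curves(g6$sequence)$right
  expect_lt(min(heal), 0.05 * max(heal))
  # determinism: same config + seed gives identical sequences
  g6b <- simulate_patient(patient_config(grade = 6, jitter_px = 0,
                                         head_sway_deg = 0, seed = 8))
  expect_identical(g6$sequence, g6b$sequence)
  g6c <- simulate_patient(patient_config(grade = 6, seed = 9))
  g6d <- simulate_patient(patient_config(grade = 6, seed = 10))
  expect_false(identical(g6c$sequence, g6d$sequence))
})

test_that("noise-free asymmetry decreases strictly with residual fraction", {
  fracs <- default_residual_fractions()
  d <- vapply(1:6, function(g)
    bilateral_ear_difference(simulate_patient(
      patient_config(grade = g, jitter_px = 0, head_sway_deg = 0,
                     seed = 1))$sequence), numeric(1))
  expect_true(all(diff(d) > 0))       # higher grade, larger difference
  expect_true(all(diff(fracs) <= 0))  # because residual motion shrinks
})

test_that("head sway is removed end to end by tilt correction", {
  quiet <- simulate_patient(patient_config(grade = 4, jitter_px = 0,
                                           head_sway_deg = 0, seed = 6))
  swayed <- simulate_patient(patient_config(grade = 4, jitter_px = 0,
                                            head_sway_deg = 12, seed = 6))
  expect_lt(abs(bilateral_ear_difference(quiet$sequence) -
                bilateral_ear_difference(swayed$sequence)), 1e-6)
})

test_that("cohorts regenerate identically and cover all grades", {
  a <- generate_cohort(2, base_seed = 77)
  b <- generate_cohort(2, base_seed = 77)
  expect_length(a, 12)
  expect_identical(vapply(a, `[[`, 1L, "grade"), rep(1:6, each = 2))
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(2, base_seed = 78)))
  expect_error(generate_cohort(0), "n_per_grade")
})

test_that("grade ordering of cohort medians is robust across reseeds", {
  # Monte-Carlo property: ordering of per-grade medians holds in >= 95%
  # of reseeded small cohorts at default noise
  ok <- vapply(1:20, function(s) {
    co <- generate_cohort(5, base_seed = 1000 + s)
    d <- vapply(co, function(x) bilateral_ear_difference(x$sequence),
                numeric(1))
    g <- vapply(co, `[[`, 1L, "grade")
    all(diff(tapply(d, g, median)) > 0)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("rendering is deterministic and region intensities separate", {
  tf <- template_face()
  p <- tf$points * 0.6  # fit the 200px-nominal template into 128px
  lm <- landmark_set(p)
  r1 <- render_face_image(lm, 128, seed = 3)
  r2 <- render_face_image(lm, 128, seed = 3)
  expect_identical(r1$image, r2$image)
  expect_false(identical(r1$image, render_face_image(lm, 128, seed = 4)$image))
  img <- r1$image
  expect_true(all(img >= 0 & img <= 255))
  # eye region much darker than cheek skin
  eye_px <- img[round(0.6 * 90) + (-1:1), round(0.6 * 65) + (-1:1)]
  cheek_px <- img[round(0.6 * 140) + (-1:1), round(0.6 * 65) + (-1:1)]
  expect_gte(mean(cheek_px) - mean(eye_px), 30)
  expect_error(render_face_image(tf, 128), "outside")
  expect_error(render_face_image(lm, 32), ">= 64")
})

test_that("closed eyes render with a collapsed eye polygon", {
  open_h <- diff(range(lm_pt(template_face(), 36:41)[, 2]))
  closed <- simulate_patient(patient_config(grade = 1, jitter_px = 0,
                                            head_sway_deg = 0, seed = 1))
  mid <- closed$sequence$frames[[16]]  # peak closure
  closed_h <- diff(range(lm_pt(mid, 36:41)[, 2]))
  expect_lt(closed_h / open_h, 0.2)
})

test_that("face dataset generation is seeded and well-formed", {
  ds <- small_face_dataset()
  expect_length(ds$images, 14)
  expect_true(all(vapply(ds$shapes, inherits, TRUE, "landmark_set")))
  for (i in c(1, 7)) {
    expect_true(all(ds$shapes[[i]]$points >= 0 &
                    ds$shapes[[i]]$points <= 96))
    expect_identical(dim(ds$images[[i]]), c(96L, 96L))
  }
  ds2 <- generate_face_dataset(3, size_px = 96, seed = 42)
  expect_identical(ds2$images[[2]], ds$images[[2]])
})
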