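test_that("NME matches its defining arithmetic", {
  tf <- template_face()
  expect_equal(nme(tf, tf), 0)
  # single evaluated point offset by 2 px, interocular distance 20 px
  p <- tf$points
  p[, 1] <- (p[, 1] - 100) * 20 / 70 + 100   # rescale so d = 20
  p[, 2] <- (p[, 2] - 90) * 20 / 70 + 90
  truth <- landmark_set(p)
  pred_p <- p
  pred_p[1, ] <- pred_p[1, ] + c(2, 0)
  expect_equal(nme(landmark_set(pred_p), truth, point_subset = 0L), 0.1)
  # eye-subset NME equals a direct arithmetic oracle
  set.seed(13)
  noisy <- landmark_set(p + matrix(rnorm(136, sd = 0.5), 68, 2))
  d <- interocular_distance(truth)
  manual <- mean(sqrt(rowSums((lm_pt(noisy, 36:47) -
                               lm_pt(truth, 36:47))^2))) / d
  expect_equal(nme(noisy, truth, point_subset = 36:47), manual)
})

test_that("augmentation multiplies the set and keeps image/shape in sync", {
  ds <- small_face_dataset()
  aug <- augment_training_set(ds$images[1:3], ds$shapes[1:3], factor = 4,
                              seed = 5)
  expect_length(aug$images, 12)
  expect_length(aug$shapes, 12)
  # first copy of each input is the identity
  expect_identical(aug$images[[1]], ds$images[[1]])
  expect_identical(aug$shapes[[5]]$points, ds$shapes[[2]]$points)
  # factor 1: pure copies
  id <- augment_training_set(ds$images[1:2], ds$shapes[1:2], factor = 1,
                             seed = 5)
  expect_identical(id$images, ds$images[1:2])
  # deterministic under the seed
  aug2 <- augment_training_set(ds$images[1:3], ds$shapes[1:3], factor = 4,
                               seed = 5)
  expect_identical(aug$shapes[[4]]$points, aug2$shapes[[4]]$points)
  expect_identical(aug$images[[4]], aug2$images[[4]])
  expect_error(augment_training_set(ds$images, ds$shapes, factor = 0),
               "factor")
})

test_that("initial sample generation counts and aligns correctly", {
  ds <- small_face_dataset()
  s <- generate_initial_samples(ds$images[1:5], ds$shapes[1:5],
                                n_initializations = 3, seed = 2)
  expect_length(s, 15)
  # residual is zero iff current equals target
  resid <- s[[1]]$target - s[[1]]$current
  expect_gt(max(abs(resid)), 0)
  # mean-shape init returns exactly the aligned mean shape
  sm <- generate_initial_samples(ds$images[1:2], ds$shapes[1:2],
                                 n_initializations = 1, seed = 2,
                                 init = "mean_shape")
  mean_shape <- Reduce(`+`, lapply(ds$shapes[1:2], `[[`, "points")) / 2
  expected <- earasym:::align_shape_to_box(mean_shape,
                                           face_box(ds$shapes[[1]]))
  expect_equal(sm[[1]]$current, expected, ignore_attr = TRUE)
  expect_error(generate_initial_samples(ds$images[1], ds$shapes[1],
                                        n_initializations = 2),
               "at least 2")
})

test_that("cascade training reduces NME and folds stage by stage", {
  ds <- small_face_dataset()
  s <- generate_initial_samples(ds$images[1:10], ds$shapes[1:10],
                                n_initializations = 2, seed = 3)
  m <- train_cascade(s, stages = 3, trees_per_stage = 25, depth = 3,
                     learning_rate = 0.2, feature_pool_size = 80, seed = 3)
  # training NME non-increasing tree by tree, stage by stage
  expect_true(all(diff(m$nme_trace) <= 1e-12))
  expect_true(all(diff(m$stage_nme) <= 1e-12))
  expect_lt(tail(m$stage_nme, 1), m$nme_trace[1])
  # prediction fold: t+1 stage output = t stage output + stage update
  img <- ds$images[[11]]
  box <- earasym:::clip_box(face_box(ds$shapes[[11]]), 96, 96)
  for (t_stage in 0:2) {
    p_t <- predict_landmarks(m, img, box, n_stages = t_stage)
    p_t1 <- predict_landmarks(m, img, box, n_stages = t_stage + 1)
    st <- m$stages[[t_stage + 1]]
    featvec <- earasym:::extract_features(img, p_t$points, st$pool,
                                          m$mean_shape)
    upd <- Reduce(`+`, lapply(st$trees, earasym:::traverse_tree,
                              featvec = featvec))
    expect_identical(p_t1$points,
                     p_t$points + earasym:::unflatten_shape(upd))
  }
  # zero stages: the aligned mean shape
  p0 <- predict_landmarks(m, img, box, n_stages = 0)
  expect_equal(p0$points, earasym:::align_shape_to_box(m$mean_shape, box),
               ignore_attr = TRUE)
  # determinism of prediction
  expect_identical(predict_landmarks(m, img, box)$points,
                   predict_landmarks(m, img, box)$points)
  expect_error(predict_landmarks(m, img, c(left = -5, top = 0, width = 200,
                                           height = 50)), "outside")
})

test_that("zero learning rate is an exact no-op cascade", {
  ds <- small_face_dataset()
  s <- generate_initial_samples(ds$images[1:6], ds$shapes[1:6],
                                n_initializations = 1, seed = 4)
  m0 <- train_cascade(s, stages = 2, trees_per_stage = 5, depth = 2,
                      learning_rate = 0, feature_pool_size = 40, seed = 4)
  expect_equal(diff(range(m0$nme_trace)), 0)
  box <- earasym:::clip_box(face_box(ds$shapes[[7]]), 96, 96)
  pred <- predict_landmarks(m0, ds$images[[7]], box)
  init <- earasym:::align_shape_to_box(m0$mean_shape, box)
  expect_identical(unname(pred$points), unname(init))
})

test_that("overfitting a single repeated image drives training NME down", {
  ds <- small_face_dataset()
  imgs <- rep(ds$images[1], 4)
  shps <- rep(ds$shapes[1], 4)
  s <- generate_initial_samples(imgs, shps, n_initializations = 1, seed = 6)
  m <- train_cascade(s, stages = 6, trees_per_stage = 40, depth = 3,
                     learning_rate = 0.3, feature_pool_size = 60, seed = 6)
  expect_lt(tail(m$stage_nme, 1), 0.01)
})

test_that("model serialization round-trips to identical predictions", {
  ds <- small_face_dataset()
  s <- generate_initial_samples(ds$images[1:8], ds$shapes[1:8],
                                n_initializations = 1, seed = 7)
  m <- train_cascade(s, stages = 2, trees_per_stage = 10, depth = 3,
                     feature_pool_size = 60, seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_ert_model(m, path)
  m2 <- read_ert_model(path)
  img <- ds$images[[9]]
  box <- earasym:::clip_box(face_box(ds$shapes[[9]]), 96, 96)
  expect_identical(predict_landmarks(m, img, box)$points,
                   predict_landmarks(m2, img, box)$points)
  expect_error(read_ert_model(withr::local_tempfile(lines = "{}",
                                                    fileext = ".json")),
               "not an earasym ERT model")
})

test_that("grid search returns the argmin cell and the full table", {
  ds <- small_face_dataset()
  train <- list(images = ds$images[1:8], shapes = ds$shapes[1:8])
  test <- list(images = ds$images[9:11], shapes = ds$shapes[9:11])
  gs <- grid_search(train, test, depths = c(2, 3),
                    learning_rates = c(0.1, 0.5),
                    stages = 2, trees_per_stage = 10,
                    feature_pool_size = 40, seed = 8)
  expect_identical(nrow(gs$table), 4L)
  expect_equal(gs$best$nme, min(gs$table$nme))
  expect_s3_class(gs$best_model, "ert_model")
  # grid of size 1 returns that model
  g1 <- grid_search(train, test, depths = 3, learning_rates = 0.2,
                    stages = 1, trees_per_stage = 5,
                    feature_pool_size = 40, seed = 8)
  expect_identical(nrow(g1$table), 1L)
  expect_error(grid_search(train, test, depths = numeric(0)), "empty")
})

test_that("incorrect detections are flagged with and without truth", {
  tf <- template_face()
  # exact agreement never flags
  expect_false(flag_incorrect_detection(tf, tf, threshold = 1e-9)$flagged)
  # both eyes collapsed onto the nose tip vs open-eye truth
  p <- tf$points
  p[37:48, 1] <- 100; p[37:48, 2] <- 133
  collapsed <- landmark_set(p)
  res <- flag_incorrect_detection(collapsed, tf)
  expect_true(res$flagged)
  expect_match(res$reason, "eye NME")
  # without truth: eye taller than wide
  q <- tf$points
  q[c(38, 39, 41, 42), 2] <- c(60, 60, 120, 120)  # indices 37,38,40,41
  res2 <- flag_incorrect_detection(landmark_set(q))
  expect_true(res2$flagged)
  expect_match(res2$reason, "taller")
  # without truth: a clean face passes
  expect_false(flag_incorrect_detection(tf)$flagged)
  # self-intersecting contour
  z <- tf$points
  z[38, ] <- c(72, 95); z[41, ] <- c(58, 85)  # swap 37 and 40 heights
  res3 <- flag_incorrect_detection(landmark_set(z))
  expect_true(res3$flagged)
  expect_error(flag_incorrect_detection(tf, tf, threshold = 0), "positive")
})

test_that("flagging recovers injected corrupt detections", {
  # 30 clean faces + 10% corrupted; recall of the truth-based flag >= 0.9
  set.seed(31)
  tf <- template_face()
  n <- 30
  corrupt <- seq_len(n) <= 3
  flags <- vapply(seq_len(n), function(i) {
    p <- tf$points + matrix(rnorm(136, sd = 0.4), 68, 2)
    if (corrupt[i]) {
      rows <- sample(37:48, 6)           # scatter eye landmarks
      p[rows, ] <- p[rows, ] + matrix(runif(12, 8, 20), 6, 2)
    }
    flag_incorrect_detection(landmark_set(p), tf)$flagged
  }, logical(1))
  expect_gte(sum(flags & corrupt) / sum(corrupt), 0.9)
  expect_lte(sum(flags & !corrupt), 2)   # few false alarms at default
})
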