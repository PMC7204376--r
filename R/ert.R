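# Desk-scale cascaded ensemble-of-regression-trees (ERT) landmark
# detector. A cascade of T stages refines a 68-point shape estimate:
#
#   S^{t+1} = S^t + r_t(I, S^t)
#
# where each update r_t is a gradient-boosted ensemble of K shallow
# regression trees splitting on thresholded differences of image
# intensities at two shape-indexed pixel locations. Pixel locations are
# stored as (nearest-landmark index, offset in mean-shape coordinates)
# and warped to the current shape through a least-squares similarity
# transform, which keeps features pose-invariant. Leaf values are
# shrinkage-scaled mean residuals (least-squares fit), so the training
# residual sum of squares is non-increasing tree by tree.
#
# Shapes are flattened column-major (all x, then all y), 136 values.

flatten_shape <- function(points) as.vector(points)
unflatten_shape <- function(v) matrix(v, 68, 2,
                                      dimnames = list(NULL, c("x", "y")))

#' Normalized mean error between two landmark sets
#'
#' Mean over the evaluated points of the Euclidean prediction error,
#' divided by the ground truth's interocular distance -- the standard
#' evaluation metric of face alignment. `squared = TRUE` gives the
#' literal squared-norm variant for sensitivity checks; it is not scale
#' normalized and is not used by default.
#'
#' @param predicted,truth [landmark_set()] objects.
#' @param point_subset optional 0-based indices to evaluate (e.g. `36:47`
#'   for the eyes); default all 68.
#' @param squared use squared per-point norms instead of the standard
#'   Euclidean distance.
#' @return non-negative scalar; 0 iff the subsets agree exactly.
#' @export
nme <- function(predicted, truth, point_subset = NULL, squared = FALSE) {
  stopifnot(inherits(predicted, "landmark_set"),
            inherits(truth, "landmark_set"))
  d <- interocular_distance(truth)
  idx <- if (is.null(point_subset)) 0:67 else as.integer(point_subset)
  dif <- lm_pt(predicted, idx) - lm_pt(truth, idx)
  err <- sqrt(rowSums(dif^2))
  if (squared) err <- err^2
  mean(err) / d
}

#' Padded bounding box of a landmark set
#'
#' @param lm a [landmark_set()].
#' @param pad padding as a fraction of the tight box's width/height.
#' @return named vector `left, top, width, height`.
#' @export
face_box <- function(lm, pad = 0.2) {
  r <- unname(apply(lm$points, 2, range))
  w <- r[2, 1] - r[1, 1]; h <- r[2, 2] - r[1, 2]
  c(left = r[1, 1] - pad * w, top = r[1, 2] - pad * h,
    width = (1 + 2 * pad) * w, height = (1 + 2 * pad) * h)
}

# Intersect a face box with the image canvas
clip_box <- function(box, width, height) {
  l <- max(box[["left"]], 0); t <- max(box[["top"]], 0)
  r <- min(box[["left"]] + box[["width"]], width)
  b <- min(box[["top"]] + box[["height"]], height)
  c(left = l, top = t, width = r - l, height = b - t)
}

# Uniform-scale alignment of a reference shape into a face box
align_shape_to_box <- function(shape, box) {
  r <- apply(shape, 2, range)
  s <- min(box["width"] / (r[2, 1] - r[1, 1]),
           box["height"] / (r[2, 2] - r[1, 2]))
  ctr_shape <- colMeans(r)
  ctr_box <- c(box["left"] + box["width"] / 2, box["top"] + box["height"] / 2)
  sweep(sweep(shape, 2, ctr_shape) * s, 2, ctr_box, "+")
}

#' Augment an annotated training set by random similarity deformation
#'
#' Produces `factor` copies of every (image, shape) pair; the first copy
#' is the identity and the rest apply a seeded random rotation, scale and
#' translation consistently to the image (nearest-neighbour resampling,
#' edge clamp) and its landmarks. Small annotated sets overfit cascade
#' training badly, so amplification of this kind is standard practice.
#'
#' @param images list of grayscale matrices.
#' @param shapes parallel list of [landmark_set()]s.
#' @param factor amplification factor (>= 1).
#' @param seed RNG seed; the augmented set is reproducible.
#' @param max_rot_deg,scale_range,max_shift_frac perturbation ranges.
#' @return list with lists `images` and `shapes` of length
#'   `factor * length(images)`.
#' @export
augment_training_set <- function(images, shapes, factor = 10L, seed = 1L,
                                 max_rot_deg = 10, scale_range = c(0.9, 1.1),
                                 max_shift_frac = 0.03) {
  if (factor < 1) stop("factor must be >= 1")
  stopifnot(length(images) == length(shapes))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out_i <- vector("list", factor * length(images))
  out_s <- vector("list", factor * length(images))
  k <- 0L
  for (i in seq_along(images)) {
    img <- images[[i]]; shp <- shapes[[i]]
    for (f in seq_len(factor)) {
      k <- k + 1L
      if (f == 1L) {
        out_i[[k]] <- img; out_s[[k]] <- shp
        next
      }
      ang <- runif(1, -max_rot_deg, max_rot_deg) * pi / 180
      s <- runif(1, scale_range[1], scale_range[2])
      shift <- runif(2, -max_shift_frac, max_shift_frac) *
        c(ncol(img), nrow(img))
      ctr <- c(ncol(img), nrow(img)) / 2
      A <- s * matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      t_vec <- ctr + shift - as.vector(A %*% ctr)
      trans <- list(A = A, t = t_vec)
      out_s[[k]] <- landmark_set(apply_similarity(trans, shp$points),
                                 frame_index = shp$frame_index,
                                 source = shp$source)
      out_i[[k]] <- warp_image_similarity(img, trans)
    }
  }
  list(images = out_i, shapes = out_s)
}

# Inverse-map nearest-neighbour similarity warp with edge clamping
warp_image_similarity <- function(img, trans) {
  ny <- nrow(img); nx <- ncol(img)
  grid <- cbind(rep(seq_len(nx), times = ny), rep(seq_len(ny), each = nx))
  Ainv <- solve(trans$A)
  src <- sweep(grid, 2, trans$t) %*% t(Ainv)
  xi <- pmin(pmax(round(src[, 1]), 1L), nx)
  yi <- pmin(pmax(round(src[, 2]), 1L), ny)
  matrix(img[cbind(yi, xi)], ny, nx, byrow = TRUE)
}

#' Generate initialized training samples for cascade training
#'
#' Each image contributes `n_initializations` samples whose starting shape
#' is either another training image's shape or the mean shape, similarity
#' aligned into the image's (ground-truth, padded) face box. Randomized
#' initial shapes teach the cascade to pull a wide basin of starting
#' points onto the target.
#'
#' @inheritParams augment_training_set
#' @param n_initializations samples per image.
#' @param init `"random_shape"` (default) or `"mean_shape"`.
#' @param box_pad face-box padding fraction.
#' @return list of samples, each `list(image, current, target)` with
#'   shapes as 68 x 2 matrices.
#' @export
generate_initial_samples <- function(images, shapes, n_initializations = 1L,
                                     seed = 1L,
                                     init = c("random_shape", "mean_shape"),
                                     box_pad = 0.2) {
  init <- match.arg(init)
  if (n_initializations < 1) stop("n_initializations must be >= 1")
  stopifnot(length(images) == length(shapes))
  if (init == "random_shape" && n_initializations > 1L &&
      length(shapes) < 2L)
    stop("random-shape initialization with n_initializations > 1 needs ",
         "at least 2 training shapes")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  mean_shape <- Reduce(`+`, lapply(shapes, `[[`, "points")) / length(shapes)
  samples <- vector("list", length(images) * n_initializations)
  k <- 0L
  for (i in seq_along(images)) {
    box <- face_box(shapes[[i]], pad = box_pad)
    for (j in seq_len(n_initializations)) {
      k <- k + 1L
      src <- if (init == "mean_shape" || length(shapes) < 2L) mean_shape
      else shapes[[sample(setdiff(seq_along(shapes), i), 1L)]]$points
      samples[[k]] <- list(image = images[[i]],
                           current = align_shape_to_box(src, box),
                           target = shapes[[i]]$points)
    }
  }
  samples
}

# ---- feature machinery ----------------------------------------------------

make_feature_pool <- function(mean_shape, pool_size) {
  r <- apply(mean_shape, 2, range)
  pad <- 0.1 * c(r[2, 1] - r[1, 1], r[2, 2] - r[1, 2])
  px <- runif(pool_size, r[1, 1] - pad[1], r[2, 1] + pad[1])
  py <- runif(pool_size, r[1, 2] - pad[2], r[2, 2] + pad[2])
  nearest <- vapply(seq_len(pool_size), function(p) {
    which.min((mean_shape[, 1] - px[p])^2 + (mean_shape[, 2] - py[p])^2)
  }, integer(1))
  list(lm = nearest - 1L,  # 0-based landmark index
       offset = cbind(px, py) - mean_shape[nearest, , drop = FALSE])
}

# Intensities of the pool pixels for one (image, current shape) pair
extract_features <- function(image, current, pool, mean_shape) {
  tr <- similarity_transform(mean_shape, current)
  pos <- current[pool$lm + 1L, , drop = FALSE] + pool$offset %*% t(tr$A)
  xi <- pmin(pmax(round(pos[, 1]), 1L), ncol(image))
  yi <- pmin(pmax(round(pos[, 2]), 1L), nrow(image))
  image[cbind(yi, xi)]
}

# ---- regression trees -----------------------------------------------------

# Complete binary tree of the given depth over pixel-difference features.
# feats: n x P intensity matrix; res: n x 136 residual matrix.
# Returns list(fi, fj, thr, leaf) plus the fitted (shrunken) per-sample
# prediction used to update the boosting residuals.
fit_tree <- function(feats, res, depth, learning_rate, n_candidates = 20L) {
  n_internal <- 2L^depth - 1L
  n_leaf <- 2L^depth
  P <- ncol(feats)
  fi <- integer(n_internal); fj <- integer(n_internal)
  thr <- numeric(n_internal)
  node_rows <- vector("list", n_internal + n_leaf)
  node_rows[[1L]] <- seq_len(nrow(feats))
  for (node in seq_len(n_internal)) {
    rows <- node_rows[[node]]
    best <- NULL; best_score <- -Inf
    if (length(rows) >= 2L) {
      for (cand in seq_len(n_candidates)) {
        a <- sample.int(P, 1L); b <- sample.int(P, 1L)
        if (a == b) next
        f <- feats[rows, a] - feats[rows, b]
        rng <- range(f)
        if (rng[1] == rng[2]) next
        tau <- runif(1, rng[1], rng[2])
        left <- f < tau
        nl <- sum(left); nr <- length(rows) - nl
        if (nl == 0L || nr == 0L) next
        sl <- colSums(res[rows[left], , drop = FALSE])
        sr <- colSums(res[rows[!left], , drop = FALSE])
        score <- sum(sl^2) / nl + sum(sr^2) / nr
        if (score > best_score) {
          best_score <- score
          best <- list(a = a, b = b, tau = tau, left = left)
        }
      }
    }
    if (is.null(best)) {
      # degenerate node: send everything left
      fi[node] <- 1L; fj[node] <- 1L; thr[node] <- Inf
      node_rows[[2L * node]] <- rows
      node_rows[[2L * node + 1L]] <- integer(0)
    } else {
      fi[node] <- best$a; fj[node] <- best$b; thr[node] <- best$tau
      node_rows[[2L * node]] <- rows[best$left]
      node_rows[[2L * node + 1L]] <- rows[!best$left]
    }
  }
  leaf <- matrix(0, n_leaf, ncol(res))
  pred <- matrix(0, nrow(feats), ncol(res))
  for (l in seq_len(n_leaf)) {
    rows <- node_rows[[n_internal + l]]
    if (length(rows) > 0L) {
      leaf[l, ] <- learning_rate * colMeans(res[rows, , drop = FALSE])
      pred[rows, ] <- matrix(leaf[l, ], length(rows), ncol(res),
                             byrow = TRUE)
    }
  }
  list(fi = fi, fj = fj, thr = thr, leaf = leaf, .pred = pred)
}

traverse_tree <- function(tree, featvec) {
  n_internal <- length(tree$fi)
  node <- 1L
  while (node <= n_internal) {
    d <- featvec[tree$fi[node]] - featvec[tree$fj[node]]
    node <- 2L * node + (d >= tree$thr[node])
  }
  tree$leaf[node - n_internal, ]
}

# ---- training -------------------------------------------------------------

sample_nme <- function(res_flat, d_i) {
  # res_flat: n x 136, d_i: per-sample interocular distance
  per_pt <- sqrt(res_flat[, 1:68, drop = FALSE]^2 +
                 res_flat[, 69:136, drop = FALSE]^2)
  mean(rowMeans(per_pt) / d_i)
}

#' Train a cascaded regression-tree landmark detector
#'
#' Fits `stages` cascade levels; each level extracts shape-indexed
#' pixel-difference features once, then boosts `trees_per_stage` depth-F
#' regression trees against the shape residuals (target - current),
#' least-squares leaf values scaled by the shrinkage `learning_rate`.
#' After each level, every sample's current shape absorbs the level's
#' summed updates. The per-tree training NME trace is recorded.
#'
#' @param samples training samples from [generate_initial_samples()].
#' @param stages cascade levels T.
#' @param trees_per_stage trees K per level.
#' @param depth tree depth F.
#' @param learning_rate shrinkage in (0, 1]; 0 is allowed and makes the
#'   cascade a no-op (useful as a control).
#' @param feature_pool_size candidate pixel locations per level.
#' @param n_candidate_splits random (pixel pair, threshold) proposals per
#'   tree node.
#' @param seed RNG seed for pools and split proposals.
#' @return object of class `ert_model`: mean shape, per-stage pools and
#'   trees, hyperparameters, and `nme_trace` / `stage_nme` diagnostics.
#' @export
train_cascade <- function(samples, stages = 6L, trees_per_stage = 100L,
                          depth = 4L, learning_rate = 0.1,
                          feature_pool_size = 200L,
                          n_candidate_splits = 20L, seed = 1L) {
  if (length(samples) < 2L) stop("need at least 2 training samples")
  if (depth < 1) stop("depth must be >= 1")
  if (learning_rate < 0 || learning_rate > 1)
    stop("learning_rate must be in [0, 1]")
  for (s in samples)
    if (!all(is.finite(s$image))) stop("non-finite image intensities")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- length(samples)
  mean_shape <- Reduce(`+`, lapply(samples, `[[`, "target")) / n
  current <- lapply(samples, `[[`, "current")
  target_flat <- t(vapply(samples, function(s) flatten_shape(s$target),
                          numeric(136)))
  d_i <- vapply(samples, function(s)
    interocular_distance(landmark_set(s$target)), numeric(1))
  res <- target_flat - t(vapply(current, flatten_shape, numeric(136)))
  nme_trace <- numeric(0)
  stage_nme <- numeric(stages)
  stage_list <- vector("list", stages)
  for (t_stage in seq_len(stages)) {
    pool <- make_feature_pool(mean_shape, feature_pool_size)
    feats <- t(vapply(seq_len(n), function(s)
      extract_features(samples[[s]]$image, current[[s]], pool, mean_shape),
      numeric(feature_pool_size)))
    trees <- vector("list", trees_per_stage)
    for (k in seq_len(trees_per_stage)) {
      tr <- fit_tree(feats, res, depth, learning_rate, n_candidate_splits)
      res <- res - tr$.pred
      tr$.pred <- NULL
      trees[[k]] <- tr
      nme_trace <- c(nme_trace, sample_nme(res, d_i))
    }
    current <- lapply(seq_len(n), function(s)
      unflatten_shape(target_flat[s, ] - res[s, ]))
    stage_nme[t_stage] <- sample_nme(res, d_i)
    stage_list[[t_stage]] <- list(pool = pool, trees = trees)
  }
  structure(list(version = "earasym-ert-1", mean_shape = mean_shape,
                 stages = stage_list, depth = as.integer(depth),
                 trees_per_stage = as.integer(trees_per_stage),
                 learning_rate = learning_rate,
                 feature_pool_size = as.integer(feature_pool_size),
                 seed = as.integer(seed),
                 nme_trace = nme_trace, stage_nme = stage_nme),
            class = "ert_model")
}

#' @export
print.ert_model <- function(x, ...) {
  cat(sprintf(
    "ERT landmark detector: %d stages x %d trees (depth %d, shrinkage %g)\n",
    length(x$stages), x$trees_per_stage, x$depth, x$learning_rate))
  if (length(x$stage_nme))
    cat("  final training NME:", format(tail(x$stage_nme, 1)), "\n")
  invisible(x)
}

#' Predict 68 landmarks on an image
#'
#' Aligns the model's mean shape into `box` and folds the cascade:
#' each stage adds its ensemble's output to the current shape estimate.
#' Deterministic given model and input.
#'
#' @param model an `ert_model`.
#' @param image grayscale matrix (rows = y).
#' @param box face box `c(left, top, width, height)`; default the whole
#'   image.
#' @param n_stages fold only the first `n_stages` levels (diagnostics);
#'   0 returns the aligned mean shape.
#' @return a [landmark_set()] with `source = "detected"`.
#' @export
predict_landmarks <- function(model, image, box = NULL, n_stages = NULL) {
  stopifnot(inherits(model, "ert_model"))
  if (is.null(box))
    box <- c(left = 0, top = 0, width = ncol(image), height = nrow(image))
  if (box["left"] < 0 || box["top"] < 0 ||
      box["left"] + box["width"] > ncol(image) ||
      box["top"] + box["height"] > nrow(image))
    stop("face box extends outside the image")
  if (is.null(n_stages)) n_stages <- length(model$stages)
  current <- align_shape_to_box(model$mean_shape, box)
  for (t_stage in seq_len(n_stages)) {
    st <- model$stages[[t_stage]]
    featvec <- extract_features(image, current, st$pool, model$mean_shape)
    upd <- numeric(136)
    for (tree in st$trees) upd <- upd + traverse_tree(tree, featvec)
    current <- current + unflatten_shape(upd)
  }
  landmark_set(current, frame_index = 0L, source = "detected")
}

#' Hyperparameter grid search for the detector
#'
#' Trains one cascade per (tree depth, shrinkage) pair and scores each on
#' the held-out test faces by mean NME; returns the winner and the full
#' table.
#'
#' @param train,test lists with parallel `images` and `shapes` elements;
#'   the two sets must be disjoint.
#' @param depths,learning_rates grid axes. The defaults follow common
#'   practice for cascade tuning: depths 2/4/5/10 and shrinkages from
#'   0.001 to 0.9.
#' @param ... passed to [train_cascade()] (e.g. `stages`,
#'   `trees_per_stage`).
#' @param n_initializations,seed sample generation controls.
#' @return list with `best_model`, `best` (its grid row) and `table`
#'   (data frame depth x learning_rate x test NME).
#' @export
grid_search <- function(train, test, depths = c(2, 4, 5, 10),
                        learning_rates = c(0.001, 0.01, 0.05, 0.1, 0.2,
                                           0.3, 0.4, 0.5, 0.6, 0.7, 0.8,
                                           0.9),
                        n_initializations = 1L, seed = 1L, ...) {
  if (length(depths) == 0L || length(learning_rates) == 0L)
    stop("empty hyperparameter grid")
  samples <- generate_initial_samples(train$images, train$shapes,
                                      n_initializations, seed = seed)
  grid <- expand.grid(depth = depths, learning_rate = learning_rates)
  grid$nme <- NA_real_
  best_model <- NULL; best_idx <- NA_integer_
  for (g in seq_len(nrow(grid))) {
    model <- train_cascade(samples, depth = grid$depth[g],
                           learning_rate = grid$learning_rate[g],
                           seed = seed, ...)
    grid$nme[g] <- mean(vapply(seq_along(test$images), function(i) {
      box <- clip_box(face_box(test$shapes[[i]]),
                      ncol(test$images[[i]]), nrow(test$images[[i]]))
      pred <- predict_landmarks(model, test$images[[i]], box)
      nme(pred, test$shapes[[i]])
    }, numeric(1)))
    if (is.na(best_idx) || grid$nme[g] < grid$nme[best_idx]) {
      best_idx <- g; best_model <- model
    }
  }
  list(best_model = best_model, best = grid[best_idx, ], table = grid)
}

# ---- detection quality control -------------------------------------------

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

contour_self_intersects <- function(pts) {
  n <- nrow(pts)
  segs <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent through the wrap-around
      if (segments_intersect(pts[segs[i, 1], ], pts[segs[i, 2], ],
                             pts[segs[j, 1], ], pts[segs[j, 2], ]))
        return(TRUE)
    }
  }
  FALSE
}

#' Flag an incorrect landmark detection
#'
#' With ground truth available, a detection is flagged when the eye-subset
#' (indices 36-47) NME exceeds `threshold`. Without truth, geometric
#' sanity checks are applied: an eye contour that self-intersects, an eye
#' taller than it is wide, or eye landmarks escaping the face's
#' normalization crop box. Flagged samples are excluded from downstream
#' EAR analysis ([apply_exclusions()]).
#'
#' @param predicted detected [landmark_set()].
#' @param truth optional annotated [landmark_set()].
#' @param threshold eye-subset NME threshold (default 0.08).
#' @return list with `flagged` (logical), `reason` (character, `""` when
#'   clean) and `eye_nme` (`NA` without truth).
#' @export
flag_incorrect_detection <- function(predicted, truth = NULL,
                                     threshold = 0.08) {
  if (threshold <= 0) stop("threshold must be positive")
  if (!is.null(truth)) {
    v <- nme(predicted, truth, point_subset = 36:47)
    return(list(flagged = v > threshold,
                reason = if (v > threshold)
                  sprintf("eye NME %.4f > %.4f", v, threshold) else "",
                eye_nme = v))
  }
  frame <- tryCatch(normalization_frame(predicted), error = function(e) NULL)
  if (is.null(frame))
    return(list(flagged = TRUE, reason = "degenerate eye geometry",
                eye_nme = NA_real_))
  for (side in c("left", "right")) {
    pts <- lm_pt(predicted, eye_point_indices(side))
    corners <- if (side == "left") c(36L, 39L) else c(42L, 45L)
    width <- sqrt(sum((lm_pt(predicted, corners[1]) -
                       lm_pt(predicted, corners[2]))^2))
    height <- diff(range(pts[, 2]))
    if (height > width)
      return(list(flagged = TRUE,
                  reason = paste(side, "eye taller than wide"),
                  eye_nme = NA_real_))
    if (contour_self_intersects(pts))
      return(list(flagged = TRUE,
                  reason = paste(side, "eye contour self-intersects"),
                  eye_nme = NA_real_))
    if (!all(in_crop_box(pts, frame)))
      return(list(flagged = TRUE,
                  reason = paste(side, "eye outside normalization box"),
                  eye_nme = NA_real_))
  }
  list(flagged = FALSE, reason = "", eye_nme = NA_real_)
}

# ---- serialization --------------------------------------------------------

#' Write an ERT model to a JSON file
#'
#' Self-describing single-file format (version header, mean shape,
#' per-stage pools and tree arrays) at full floating-point precision, so
#' a reloaded model predicts bit-identically.
#'
#' @param model an `ert_model`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_ert_model <- function(model, path) {
  stopifnot(inherits(model, "ert_model"))
  # I(17) = 17 significant digits, enough to round-trip IEEE doubles exactly
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE,
                       digits = I(17), matrix = "rowmajor")
  invisible(path)
}

#' Read an ERT model written by [write_ert_model()]
#' @param path model file.
#' @return an `ert_model`.
#' @export
read_ert_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$version) || !startsWith(obj$version, "earasym-ert"))
    stop("not an earasym ERT model file: ", path)
  as_mat <- function(rows)  # row-major nested arrays -> matrix
    do.call(rbind, lapply(rows, function(r) unlist(r, use.names = FALSE)))
  num <- function(x) as.numeric(unlist(x, use.names = FALSE))
  obj$mean_shape <- as_mat(obj$mean_shape)
  dimnames(obj$mean_shape) <- list(NULL, c("x", "y"))
  obj$stages <- lapply(obj$stages, function(st) {
    list(pool = list(lm = as.integer(unlist(st$pool$lm)),
                     offset = as_mat(st$pool$offset)),
         trees = lapply(st$trees, function(tr)
           list(fi = as.integer(unlist(tr$fi)),
                fj = as.integer(unlist(tr$fj)),
                thr = num(tr$thr), leaf = as_mat(tr$leaf))))
  })
  for (f in c("nme_trace", "stage_nme")) obj[[f]] <- num(obj[[f]])
  obj$learning_rate <- as.numeric(obj$learning_rate)
  for (f in c("depth", "trees_per_stage", "feature_pool_size", "seed"))
    obj[[f]] <- as.integer(obj[[f]])
  structure(obj, class = "ert_model")
}
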