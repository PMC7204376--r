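# Seeded generators standing in for clinical data: landmark sequences of
# synthetic patients with grade-dependent unilateral eyelid impairment,
# and procedurally rendered face-like images for detector training.
#
# The eyelid kinematics are a single smooth open-close cycle; the affected
# side performs the same trajectory attenuated by a grade-dependent
# residual fraction. The residual fractions discretize the FNGS 2.0 eye
# bands ("slight weakness >75% of normal" ... "trace movement", "no
# movement") as 1.00, 0.80, 0.55, 0.30, 0.10, 0.00 for scores 1-6 -- a
# modeling choice, fully configurable.

#' Default residual motion fraction per FNGS 2.0 eye score
#' @return named numeric vector, scores "1".."6".
#' @export
default_residual_fractions <- function() {
  c(`1` = 1.00, `2` = 0.80, `3` = 0.55, `4` = 0.30, `5` = 0.10, `6` = 0.00)
}

# Template landmark layout, mirror-symmetric about x = 100, y down,
# roughly a 200 x 200 px face. Left half + midline defined explicitly,
# right half mirrored so bilateral symmetry is exact.
template_points <- function() {
  p <- matrix(NA_real_, 68, 2)
  set_pt <- function(idx, x, y) p[idx + 1L, ] <<- c(x, y)
  # jaw, left half + chin
  jaw <- rbind(c(30, 95), c(32, 115), c(36, 134), c(42, 152), c(52, 168),
               c(65, 181), c(80, 190), c(90, 196), c(100, 198))
  for (i in 0:8) set_pt(i, jaw[i + 1, 1], jaw[i + 1, 2])
  for (i in 9:16) set_pt(i, 200 - jaw[17 - i, 1], jaw[17 - i, 2])
  # left brow 17-21; right brow mirrored
  brow <- rbind(c(48, 72), c(56, 67), c(65, 65), c(74, 67), c(82, 71))
  for (i in 17:21) set_pt(i, brow[i - 16, 1], brow[i - 16, 2])
  for (i in 22:26) set_pt(i, 200 - brow[27 - i, 1], brow[27 - i, 2])
  # nose bridge 27-30 (27 = nasal root), nostril line 31-35 (33 = tip)
  set_pt(27, 100, 85); set_pt(28, 100, 97)
  set_pt(29, 100, 109); set_pt(30, 100, 120)
  set_pt(31, 88, 128); set_pt(32, 94, 131); set_pt(33, 100, 133)
  set_pt(34, 106, 131); set_pt(35, 112, 128)
  # left eye 36-41 (36, 39 corners); right eye mirrored
  eye <- rbind(c(50, 90), c(58, 85), c(72, 85), c(80, 90),
               c(72, 95), c(58, 95))
  for (i in 36:41) set_pt(i, eye[i - 35, 1], eye[i - 35, 2])
  mirror <- c(45, 44, 43, 42, 47, 46)  # 36..41 -> image-right partners
  for (k in 1:6) set_pt(mirror[k], 200 - eye[k, 1], eye[k, 2])
  # outer mouth 48-59, inner mouth 60-67
  outer <- rbind(c(75, 158), c(84, 153), c(93, 150), c(100, 151),
                 c(107, 150), c(116, 153), c(125, 158), c(116, 165),
                 c(107, 169), c(100, 170), c(93, 169), c(84, 165))
  for (i in 48:59) set_pt(i, outer[i - 47, 1], outer[i - 47, 2])
  inner <- rbind(c(82, 158), c(92, 156), c(100, 157), c(108, 156),
                 c(118, 158), c(108, 161), c(100, 162), c(92, 161))
  for (i in 60:67) set_pt(i, inner[i - 59, 1], inner[i - 59, 2])
  p
}

#' Neutral template face
#'
#' A fixed, bilaterally mirror-symmetric 68-point neutral face with open
#' eyes, in pixel coordinates on a nominal 200 x 200 canvas (midline
#' through the nasal root and nose tip at x = 100). All synthetic patients
#' and rendered training faces derive from this layout.
#'
#' @return a [landmark_set()] with `source = "synthetic"`.
#' @export
template_face <- function() {
  landmark_set(template_points(), frame_index = 0L, source = "synthetic")
}

# y-distance between upper and lower lid rows of the template (open eye)
TEMPLATE_LID_GAP <- 10

#' Synthetic patient configuration
#'
#' @param grade FNGS 2.0 eye score 1-6 to emulate.
#' @param n_frames frames in the sequence (default 30: one second at the
#'   30 fps the pipeline targets).
#' @param closure_amplitude peak eyelid closure as a fraction of the open
#'   lid gap (default 1 = complete closure on the healthy side).
#' @param residual_fraction_map named vector mapping scores "1".."6" to
#'   the affected side's residual motion fraction; must be non-increasing
#'   with grade 1 at 1.
#' @param affected_side `"left"` or `"right"` (image side).
#' @param head_sway_deg max per-frame in-plane head rotation, degrees.
#' @param jitter_px landmark noise standard deviation, pixels.
#' @param seed RNG seed; the generated sequence is a pure function of the
#'   configuration.
#' @return list of class `synthetic_patient_config`.
#' @export
patient_config <- function(grade, n_frames = 30L, closure_amplitude = 1,
                           residual_fraction_map = default_residual_fractions(),
                           affected_side = "left", head_sway_deg = 3,
                           jitter_px = 0.3, seed = 1L) {
  if (!grade %in% 1:6) stop("grade must be an integer in 1..6")
  if (n_frames < 1) stop("n_frames must be positive")
  if (closure_amplitude <= 0 || closure_amplitude > 1)
    stop("closure_amplitude must be in (0, 1]")
  rf <- residual_fraction_map[as.character(1:6)]
  if (anyNA(rf) || any(diff(rf) > 0) || rf[1] != 1 || any(rf < 0 | rf > 1))
    stop("residual_fraction_map must cover scores 1..6, lie in [0,1], be ",
         "non-increasing, and map grade 1 to 1")
  affected_side <- match.arg(affected_side, c("left", "right"))
  if (head_sway_deg < 0) stop("head_sway_deg must be >= 0")
  if (jitter_px < 0) stop("jitter_px must be >= 0")
  structure(list(grade = as.integer(grade), n_frames = as.integer(n_frames),
                 closure_amplitude = closure_amplitude,
                 residual_fraction_map = rf,
                 affected_side = affected_side,
                 head_sway_deg = head_sway_deg, jitter_px = jitter_px,
                 seed = as.integer(seed)),
            class = "synthetic_patient_config")
}

# upper/lower lid point indices (0-based) per image side
lid_indices <- function(side) {
  if (side == "left") list(upper = c(37L, 38L), lower = c(40L, 41L))
  else list(upper = c(43L, 44L), lower = c(46L, 47L))
}

#' Simulate one synthetic patient's eye open-close sequence
#'
#' The four lid points of each eye move vertically through one smooth
#' closure cycle, displacement `A * (1 - cos(2 * pi * t / n_frames)) / 2`
#' with `A = closure_amplitude * open lid gap`; eye corners stay fixed.
#' The affected side's displacement is multiplied by the grade's residual
#' fraction, so grade 1 moves symmetrically and grade 6 keeps the affected
#' eye open throughout. Each frame then receives a seeded in-plane head
#' rotation (up to `head_sway_deg`) about the eye midpoint and Gaussian
#' landmark jitter. Deterministic given the configuration.
#'
#' @param config a [patient_config()].
#' @return list with `sequence` (a [frame_sequence()]) and `grade`.
#' @export
simulate_patient <- function(config) {
  stopifnot(inherits(config, "synthetic_patient_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  base <- template_points()
  A <- config$closure_amplitude * TEMPLATE_LID_GAP
  resid_frac <- config$residual_fraction_map[[as.character(config$grade)]]
  healthy <- if (config$affected_side == "left") "right" else "left"
  n <- config$n_frames
  frames <- lapply(seq_len(n) - 1L, function(t) {
    p <- base
    c_t <- A * (1 - cos(2 * pi * t / n)) / 2
    for (side in c("left", "right")) {
      amt <- if (side == healthy) c_t else resid_frac * c_t
      li <- lid_indices(side)
      p[li$upper + 1L, 2] <- p[li$upper + 1L, 2] + amt / 2
      p[li$lower + 1L, 2] <- p[li$lower + 1L, 2] - amt / 2
    }
    if (config$head_sway_deg > 0) {
      ang <- runif(1, -config$head_sway_deg, config$head_sway_deg) * pi / 180
      lm_tmp <- landmark_set(p)
      p <- rotate_points(p, ang, eye_midpoint(lm_tmp))
    }
    if (config$jitter_px > 0)
      p <- p + matrix(rnorm(136, sd = config$jitter_px), 68, 2)
    landmark_set(p, frame_index = t, source = "synthetic")
  })
  list(sequence = frame_sequence(frames, expression = "eye_cycle",
                                 subject_id = sprintf("synth_g%d_s%d",
                                                      config$grade,
                                                      config$seed),
                                 fps = 30),
       grade = config$grade)
}

#' Generate a synthetic patient cohort
#'
#' `n_per_grade` patients for each FNGS 2.0 eye score 1-6, with
#' per-patient seeds derived from `base_seed` and randomized affected
#' sides. Regenerates identically from the same `base_seed`.
#'
#' @param n_per_grade patients per score.
#' @param base_seed master seed.
#' @param ... overrides forwarded to [patient_config()] (e.g. `n_frames`,
#'   `jitter_px`).
#' @return list of `list(sequence, grade, subject_id)` of length
#'   `6 * n_per_grade`.
#' @export
generate_cohort <- function(n_per_grade, base_seed = 1L, ...) {
  if (n_per_grade < 1) stop("n_per_grade must be >= 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(base_seed)
  total <- 6L * n_per_grade
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  sides <- sample(c("left", "right"), total, replace = TRUE)
  out <- vector("list", total)
  i <- 0L
  for (g in 1:6) for (j in seq_len(n_per_grade)) {
    i <- i + 1L
    cfg <- patient_config(grade = g, affected_side = sides[i],
                          seed = seeds[i], ...)
    pat <- simulate_patient(cfg)
    out[[i]] <- list(sequence = pat$sequence, grade = g,
                     subject_id = sprintf("g%d_p%02d", g, j))
  }
  out
}

# even-odd point-in-polygon test, vectorized over query points
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    denom <- vy[j] - vy[i]
    if (denom != 0) {
      cross <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / denom + vx[i])
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

fill_polygon <- function(img, vx, vy, value) {
  size_y <- nrow(img); size_x <- ncol(img)
  x0 <- max(1L, floor(min(vx))); x1 <- min(size_x, ceiling(max(vx)))
  y0 <- max(1L, floor(min(vy))); y1 <- min(size_y, ceiling(max(vy)))
  if (x1 < x0 || y1 < y0) return(img)
  xs <- x0:x1; ys <- y0:y1
  grid <- expand.grid(x = xs, y = ys)
  hit <- point_in_polygon(grid$x - 0.5, grid$y - 0.5, vx, vy)
  if (any(hit)) img[cbind(grid$y[hit], grid$x[hit])] <- value
  img
}

poly_of <- function(points, idx) {
  list(x = points[idx + 1L, 1], y = points[idx + 1L, 2])
}

#' Render a face-like grayscale image from landmarks
#'
#' Deterministic procedural rendering used as the training substrate for
#' the landmark detector: smooth background gradient, skin-toned face
#' region bounded by the jaw contour plus a forehead arc, and filled
#' brow/eye/nose/mouth polygons with per-region intensities chosen so
#' pixel-difference features are informative (eye fill differs from skin
#' by far more than 30 gray levels). Seeded Gaussian pixel noise is added
#' last. Not photorealistic by design.
#'
#' @param lm a [landmark_set()] whose points all lie inside the canvas.
#' @param size_px canvas side length, >= 64.
#' @param seed noise seed.
#' @param noise_sd Gaussian pixel noise standard deviation (gray levels).
#' @return list with `image` (size_px x size_px matrix, gray 0-255, row =
#'   y) and `shape` (the input landmarks).
#' @export
render_face_image <- function(lm, size_px = 128L, seed = 1L, noise_sd = 3) {
  stopifnot(inherits(lm, "landmark_set"))
  if (size_px < 64L) stop("size_px must be >= 64")
  p <- lm$points
  if (any(p < 0 | p > size_px))
    stop("landmarks fall outside the ", size_px, " px canvas")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # background: gentle vertical gradient
  img <- matrix(rep(seq(150, 120, length.out = size_px), each = size_px),
                size_px, size_px, byrow = TRUE)
  img <- t(img)  # rows = y
  # face region: jaw contour 0-16 closed by a forehead arc
  jaw <- poly_of(p, 0:16)
  cx <- (p[1, 1] + p[17, 1]) / 2
  brow_y <- min(p[18:27, 2])
  top_y <- max(1, brow_y - 0.45 * (max(jaw$y) - brow_y))
  th <- seq(0, pi, length.out = 15)
  arc_x <- cx + (p[17, 1] - cx) * cos(th)
  arc_y <- jaw$y[17] - (jaw$y[17] - top_y) * sin(th)
  img <- fill_polygon(img, c(jaw$x, arc_x), c(jaw$y, arc_y), 205)
  # brows
  brow_l <- poly_of(p, 17:21); brow_r <- poly_of(p, 22:26)
  hb <- 0.035 * size_px
  img <- fill_polygon(img, c(brow_l$x, rev(brow_l$x)),
                      c(brow_l$y - hb / 2, rev(brow_l$y) + hb / 2), 70)
  img <- fill_polygon(img, c(brow_r$x, rev(brow_r$x)),
                      c(brow_r$y - hb / 2, rev(brow_r$y) + hb / 2), 70)
  # nose: bridge band + nostril line
  img <- fill_polygon(img, c(p[28, 1] - 2, p[28, 1] + 2,
                             p[31, 1] + 4, p[31, 1] - 4),
                      c(p[28, 2], p[28, 2], p[31, 2], p[31, 2]), 170)
  nostril <- poly_of(p, 31:35)
  img <- fill_polygon(img, c(nostril$x, rev(nostril$x)),
                      c(nostril$y - 2, rev(nostril$y) + 2), 120)
  # eyes: dark fill of the 6-point contour
  eye_l <- poly_of(p, 36:41); eye_r <- poly_of(p, 42:47)
  img <- fill_polygon(img, eye_l$x, eye_l$y, 45)
  img <- fill_polygon(img, eye_r$x, eye_r$y, 45)
  # mouth: outer contour
  mouth <- poly_of(p, 48:59)
  img <- fill_polygon(img, mouth$x, mouth$y, 95)
  if (noise_sd > 0)
    img <- img + matrix(rnorm(size_px^2, sd = noise_sd), size_px, size_px)
  img <- pmin(pmax(img, 0), 255)
  list(image = img, shape = lm)
}

#' Generate a rendered face dataset for detector training
#'
#' Each face starts from the template, receives seeded shape variation
#' (independent per-eye openness, mouth opening, brow raise) and a random
#' similarity pose (scale, rotation, translation) fitted inside the
#' canvas, and is rendered with [render_face_image()].
#'
#' @param n number of faces.
#' @param size_px canvas side length.
#' @param seed master seed.
#' @return list with parallel lists `images` and `shapes`.
#' @export
generate_face_dataset <- function(n, size_px = 96L, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  images <- vector("list", n); shapes <- vector("list", n)
  for (i in seq_len(n)) {
    p <- template_points()
    # independent eyelid openness per eye
    for (side in c("left", "right")) {
      close_amt <- runif(1, 0, 0.85) * TEMPLATE_LID_GAP
      li <- lid_indices(side)
      p[li$upper + 1L, 2] <- p[li$upper + 1L, 2] + close_amt / 2
      p[li$lower + 1L, 2] <- p[li$lower + 1L, 2] - close_amt / 2
    }
    # mouth opening and brow raise
    mouth_dy <- runif(1, -2, 6)
    p[c(56:59, 65:67) + 1L, 2] <- p[c(56:59, 65:67) + 1L, 2] + mouth_dy
    brow_dy <- runif(1, -3, 3)
    p[17:26 + 1L, 2] <- p[17:26 + 1L, 2] + brow_dy
    # similarity pose inside the canvas (template spans ~[28,172]x[63,200])
    scale <- runif(1, 0.38, 0.46) * size_px / 100
    ang <- runif(1, -8, 8) * pi / 180
    p <- rotate_points(p, ang, c(100, 115)) * scale
    span <- apply(p, 2, range)
    p[, 1] <- p[, 1] - span[1, 1] + runif(1, 1, size_px - diff(span[, 1]) - 1)
    p[, 2] <- p[, 2] - span[1, 2] + runif(1, 1, size_px - diff(span[, 2]) - 1)
    lm <- landmark_set(p, frame_index = 0L, source = "synthetic")
    images[[i]] <- render_face_image(lm, size_px,
                                     seed = sample.int(1e6, 1))$image
    shapes[[i]] <- lm
  }
  list(images = images, shapes = shapes)
}
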