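# Geometric normalization ahead of EAR computation: in-plane tilt
# correction about the eye midpoint C, and the rectangular face frame
# anchored at C with half-width d (the interocular distance), extending
# 0.5 d above and 1.5 d below C.

eye_center <- function(lm, side) {
  colMeans(lm_pt(lm, eye_point_indices(side)))
}

#' Interocular distance
#'
#' Euclidean distance between the centers of the two eye contours (mean of
#' points 36-41 vs mean of 42-47). This is the normalizer `d` of the face
#' frame and of the landmark-error metric [nme()]; the eye-center (rather
#' than outer-corner) convention is stable under eye closure.
#'
#' @param lm a [landmark_set()].
#' @return positive scalar, pixels.
#' @export
interocular_distance <- function(lm) {
  d <- sqrt(sum((eye_center(lm, "left") - eye_center(lm, "right"))^2))
  if (d <= .Machine$double.eps * 100)
    stop("degenerate geometry: the two eye centers coincide")
  d
}

eye_midpoint <- function(lm) {
  (eye_center(lm, "left") + eye_center(lm, "right")) / 2
}

# Angle of the line joining the two eye-corner midpoints; corners are used
# (not contour centers) because they do not move during eyelid closure.
tilt_angle <- function(lm) {
  cl <- colMeans(lm_pt(lm, c(36L, 39L)))
  cr <- colMeans(lm_pt(lm, c(42L, 45L)))
  v <- cr - cl
  if (sqrt(sum(v^2)) <= .Machine$double.eps * 100)
    stop("degenerate geometry: eye corners coincide")
  atan2(v[2], v[1])
}

rotate_points <- function(points, angle, center) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  out <- sweep(sweep(points, 2, center) %*% t(R), 2, center, "+")
  dimnames(out) <- dimnames(points)
  out
}

#' Correct in-plane head tilt
#'
#' Rotates every frame's 68 points about the eye midpoint C so the line
#' through the two eye-corner midpoints becomes horizontal. Patients
#' performing expression tasks often sway their heads; without this step,
#' per-frame landmark displacements mix head motion into the eyelid signal.
#' Only in-plane rotation is corrected (no 3-D pose). Idempotent.
#'
#' @param seq a [frame_sequence()].
#' @return a new, tilt-corrected `frame_sequence`; the input is unmodified.
#' @export
tilt_correct <- function(seq) {
  stopifnot(inherits(seq, "frame_sequence"))
  frames <- lapply(seq_along(seq$frames), function(i) {
    f <- seq$frames[[i]]
    ang <- tryCatch(tilt_angle(f), error = function(e)
      stop("frame ", f$frame_index, " (position ", i, "): ",
           conditionMessage(e), call. = FALSE))
    f$points <- rotate_points(f$points, -ang, eye_midpoint(f))
    f
  })
  out <- seq
  out$frames <- frames
  out
}

#' Normalization frame of a face
#'
#' The rectangular face region anchored at the eye midpoint C: width 2d
#' centred on C, extending 0.5 d above and 1.5 d below C, where d is the
#' interocular distance. Used to crop faces to a common geometry and in
#' landmark sanity checks.
#'
#' @param lm a valid, ideally tilt-corrected [landmark_set()].
#' @return list of class `normalization_frame` with fields `center` (C),
#'   `interocular` (d), `rotation_angle` (residual tilt, radians) and
#'   `crop_box` (named vector left, top, width, height).
#' @export
normalization_frame <- function(lm) {
  d <- interocular_distance(lm)
  C <- eye_midpoint(lm)
  box <- c(left = C[[1]] - d, top = C[[2]] - 0.5 * d,
           width = 2 * d, height = 2 * d)
  structure(list(center = C, interocular = d,
                 rotation_angle = tilt_angle(lm), crop_box = box),
            class = "normalization_frame")
}

in_crop_box <- function(points, frame) {
  b <- frame$crop_box
  points[, 1] >= b["left"] & points[, 1] <= b["left"] + b["width"] &
    points[, 2] >= b["top"] & points[, 2] <= b["top"] + b["height"]
}

# Least-squares similarity transform (scale-rotation + translation) taking
# `from` onto `to`; both n x 2. Returns list(s R as 2x2 scaled rotation, t).
similarity_transform <- function(from, to) {
  mf <- colMeans(from); mt <- colMeans(to)
  fc <- sweep(from, 2, mf); tc <- sweep(to, 2, mt)
  a <- sum(fc * tc) / sum(fc^2)
  b <- sum(fc[, 1] * tc[, 2] - fc[, 2] * tc[, 1]) / sum(fc^2)
  A <- matrix(c(a, b, -b, a), 2, 2)
  list(A = A, t = mt - as.vector(A %*% mf))
}

apply_similarity <- function(trans, points) {
  sweep(points %*% t(trans$A), 2, trans$t, "+")
}
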