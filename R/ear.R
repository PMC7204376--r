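# Amplified eye aspect ratio and bilateral asymmetry.
#
# EAR of one eye is the ratio of the two vertical eyelid distances to twice
# the horizontal corner distance, multiplied by an amplification factor:
# the distance from the brow reference point to the nose tip divided by the
# nose length (nasal root to tip). The factor exploits the observation that
# brow motion is also asymmetric in facial palsy, enlarging the bilateral
# EAR contrast; the nasal root and tip barely move during expression tasks,
# so the denominator is a stable within-face ruler.
#
#   left : (||LM37-LM41|| + ||LM38-LM40||) / (2 ||LM36-LM39||)
#            * ||LM19-LM33|| / ||LM27-LM33||
#   right: (||LM43-LM47|| + ||LM44-LM46||) / (2 ||LM42-LM45||)
#            * ||LM24-LM33|| / ||LM27-LM33||
#
# Being a ratio of distances, EAR is invariant to translation, rotation and
# uniform scaling of the landmark set.

dist2 <- function(lm, i, j) {
  sqrt(sum((lm_pt(lm, i) - lm_pt(lm, j))^2))
}

#' Amplified eye aspect ratio of one eye
#'
#' @param lm a [landmark_set()].
#' @param side `"left"` or `"right"` (image side).
#' @return non-negative scalar; 0 for a fully closed eye.
#' @export
ear_one_eye <- function(lm, side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") {
    v1 <- dist2(lm, 37L, 41L); v2 <- dist2(lm, 38L, 40L)
    h <- dist2(lm, 36L, 39L); brow <- 19L
  } else {
    v1 <- dist2(lm, 43L, 47L); v2 <- dist2(lm, 44L, 46L)
    h <- dist2(lm, 42L, 45L); brow <- 24L
  }
  nose <- dist2(lm, 27L, 33L)
  if (h <= .Machine$double.eps * 100)
    stop("degenerate geometry: zero eye-corner distance (", side, " eye)")
  if (nose <= .Machine$double.eps * 100)
    stop("degenerate geometry: zero nose length")
  (v1 + v2) / (2 * h) * dist2(lm, brow, 33L) / nose
}

#' Per-frame EAR curves of both eyes
#'
#' Evaluates the amplified EAR for each eye in every frame of a movement
#' image series, yielding the two trajectory curves P (left) and Q (right)
#' whose discrepancy quantifies bilateral asymmetry.
#'
#' @param seq a [frame_sequence()].
#' @param apply_tilt_correction correct in-plane head tilt first (default
#'   `TRUE`; EAR itself is rotation-invariant, so this mainly matters when
#'   curves are exported alongside cropped images).
#' @return object of class `ear_curve_pair`: list with numeric vectors
#'   `left`, `right` (equal length = frame count) and `frechet_distance`
#'   (`NA` until [bilateral_ear_difference()] fills it).
#' @export
ear_curves <- function(seq, apply_tilt_correction = TRUE) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (length(seq$frames) == 0L) stop("empty frame sequence")
  if (apply_tilt_correction) seq <- tilt_correct(seq)
  ev <- function(side) vapply(seq_along(seq$frames), function(i) {
    tryCatch(ear_one_eye(seq$frames[[i]], side), error = function(e)
      stop("frame ", seq$frames[[i]]$frame_index, " (position ", i, "): ",
           conditionMessage(e), call. = FALSE))
  }, numeric(1))
  structure(list(left = ev("left"), right = ev("right"),
                 frechet_distance = NA_real_),
            class = "ear_curve_pair")
}

#' @export
print.ear_curve_pair <- function(x, ...) {
  cat("EAR curve pair:", length(x$left), "frames; Frechet distance:",
      if (is.na(x$frechet_distance)) "not yet computed" else
        format(x$frechet_distance), "\n")
  invisible(x)
}

#' Discrete Fréchet distance between two scalar series
#'
#' The discrete Fréchet distance of Eiter and Mannila: the minimum over all
#' monotone couplings of the two point sequences of the maximum pointwise
#' gap, computed by dynamic programming over the |P| x |Q| grid with cost
#' `|p_i - q_j|`. It is the "dog-leash" length needed to traverse both EAR
#' curves in order, and is the bilateral asymmetry statistic of this
#' package. `coupling = "identity"` instead pairs index i with index i
#' (equal lengths required) and returns the maximum per-index gap -- a
#' stricter variant exposed for sensitivity analysis.
#'
#' @param P,Q non-empty numeric vectors.
#' @param coupling `"eiter_mannila"` (default) or `"identity"`.
#' @return non-negative scalar; 0 iff a perfectly aligned traversal exists.
#' @seealso [frechet_naive()] for the brute-force reference.
#' @export
frechet_distance <- function(P, Q, coupling = c("eiter_mannila", "identity")) {
  coupling <- match.arg(coupling)
  if (length(P) == 0L || length(Q) == 0L)
    stop("Frechet distance needs non-empty series")
  if (!is.numeric(P) || !is.numeric(Q) || anyNA(P) || anyNA(Q))
    stop("series must be numeric without missing values")
  if (coupling == "identity") {
    if (length(P) != length(Q))
      stop("identity coupling requires equal-length series")
    return(max(abs(P - Q)))
  }
  n <- length(P); m <- length(Q)
  cost <- abs(outer(P, Q, "-"))
  ca <- matrix(NA_real_, n, m)
  ca[1, 1] <- cost[1, 1]
  for (i in seq_len(n)[-1]) ca[i, 1] <- max(ca[i - 1, 1], cost[i, 1])
  for (j in seq_len(m)[-1]) ca[1, j] <- max(ca[1, j - 1], cost[1, j])
  for (i in seq_len(n)[-1])
    for (j in seq_len(m)[-1])
      ca[i, j] <- max(min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]),
                      cost[i, j])
  ca[n, m]
}

#' Brute-force discrete Fréchet distance (test oracle)
#'
#' Exhaustively enumerates every monotone coupling (every lattice path from
#' (1,1) to (|P|,|Q|) with unit steps right/down/diagonal) and returns the
#' minimum over paths of the maximum pointwise gap. Exponential; guarded to
#' short series. Kept independent of the dynamic program so the two can
#' check each other.
#'
#' @param P,Q non-empty numeric vectors with `length(P) + length(Q) <= 16`.
#' @return exact discrete Fréchet distance.
#' @export
frechet_naive <- function(P, Q) {
  if (length(P) == 0L || length(Q) == 0L)
    stop("Frechet distance needs non-empty series")
  if (length(P) + length(Q) > 16L)
    stop("frechet_naive is limited to length(P) + length(Q) <= 16")
  n <- length(P); m <- length(Q)
  walk <- function(i, j, worst) {
    worst <- max(worst, abs(P[i] - Q[j]))
    if (i == n && j == m) return(worst)
    best <- Inf
    if (i < n) best <- min(best, walk(i + 1L, j, worst))
    if (j < m) best <- min(best, walk(i, j + 1L, worst))
    if (i < n && j < m) best <- min(best, walk(i + 1L, j + 1L, worst))
    best
  }
  walk(1L, 1L, -Inf)
}

#' Bilateral EAR difference of a movement sequence
#'
#' The end-to-end asymmetry statistic: the discrete Fréchet distance
#' between the left- and right-eye amplified EAR curves of the sequence.
#' Larger values mean greater disagreement between the movements of the two
#' eye regions; for a healthy, symmetric subject it is near 0, and it grows
#' with the severity of unilateral eyelid impairment.
#'
#' @inheritParams ear_curves
#' @param coupling passed to [frechet_distance()].
#' @return non-negative scalar.
#' @export
bilateral_ear_difference <- function(seq, apply_tilt_correction = TRUE,
                                     coupling = "eiter_mannila") {
  ec <- ear_curves(seq, apply_tilt_correction)
  frechet_distance(ec$left, ec$right, coupling)
}

#' Export an EAR curve pair as two-column data frames
#'
#' @param ec an `ear_curve_pair` from [ear_curves()].
#' @return list of data frames `left` and `right`, columns `frame`, `value`.
#' @export
ear_curves_as_df <- function(ec) {
  stopifnot(inherits(ec, "ear_curve_pair"))
  n <- length(ec$left)
  list(left = data.frame(frame = seq_len(n) - 1L, value = ec$left),
       right = data.frame(frame = seq_len(n) - 1L, value = ec$right))
}
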