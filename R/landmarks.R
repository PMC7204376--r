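#' @importFrom stats median cor rnorm runif sd setNames predict
#' @importFrom utils read.csv write.csv head tail
NULL

# Landmark indices follow the 0-based iBUG 68-point convention:
#   0-16 jaw, 17-21 left brow, 22-26 right brow, 27-30 nose bridge
#   (27 = nasal root), 31-35 nostrils (33 = nose tip), 36-41 image-left
#   eye contour, 42-47 image-right eye contour, 48-67 mouth.
# Row r of the 68 x 2 point matrix holds landmark index r - 1; pixel
# coordinates, origin top-left, y increasing downward. "Left"/"right"
# throughout means image-left/image-right (observer view).

#' Construct a landmark set
#'
#' A `landmark_set` is the atomic geometric observation: the 68 named 2-D
#' facial points of one frame, in pixel coordinates (origin top-left, y
#' down), indexed 0-67 in the iBUG convention.
#'
#' @param points numeric 68 x 2 matrix (columns x, y); row `r` is landmark
#'   index `r - 1`.
#' @param frame_index non-negative integer position of the frame in its
#'   sequence.
#' @param source one of `"annotated"`, `"detected"`, `"synthetic"`.
#' @return object of class `landmark_set`.
#' @seealso [lm_pt()], [eye_point_indices()], [frame_sequence()]
#' @export
landmark_set <- function(points, frame_index = 0L, source = "synthetic") {
  points <- as.matrix(points)
  if (nrow(points) != 68L || ncol(points) != 2L)
    stop("a landmark set needs exactly 68 (x, y) points, got ",
         nrow(points), " x ", ncol(points))
  if (!all(is.finite(points)))
    stop("landmark coordinates must all be finite")
  if (length(frame_index) != 1L || is.na(frame_index) || frame_index < 0)
    stop("frame_index must be a single non-negative integer")
  source <- match.arg(source, c("annotated", "detected", "synthetic"))
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(list(points = points,
                 frame_index = as.integer(frame_index),
                 source = source),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("68-point landmark set (frame", x$frame_index,
      ", source:", x$source, ")\n")
  rng <- apply(x$points, 2, range)
  cat(sprintf("  x in [%.2f, %.2f], y in [%.2f, %.2f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2]))
  invisible(x)
}

#' Look up landmark coordinates by 0-based index
#'
#' @param lm a [landmark_set()].
#' @param idx 0-based landmark indices (0-67), scalar or vector.
#' @return numeric matrix with one row per index, columns x, y.
#' @export
lm_pt <- function(lm, idx) {
  stopifnot(inherits(lm, "landmark_set"))
  if (any(idx < 0L | idx > 67L)) stop("landmark indices must be in 0..67")
  lm$points[idx + 1L, , drop = FALSE]
}

#' Contour indices of one eye
#'
#' The six 0-based contour indices of an eye: 36-41 for the image-left eye,
#' 42-47 for the image-right eye. Indices 36/39 and 42/45 are the eye
#' corners.
#'
#' @param side `"left"` or `"right"` (image side, observer view).
#' @return integer vector of six 0-based indices.
#' @export
eye_point_indices <- function(side) {
  side <- match.arg(side, c("left", "right"))
  if (side == "left") 36:41 else 42:47
}

#' Construct a frame sequence
#'
#' An ordered series of [landmark_set()]s for one subject performing one
#' expression task (the movement image series).
#'
#' @param frames list of `landmark_set` objects with strictly increasing
#'   `frame_index`.
#' @param expression task label, one of `"open_eye"`, `"closed_eye"`,
#'   `"bare_teeth"`, `"bulge_mouth"`, `"eye_cycle"`.
#' @param subject_id subject identifier string.
#' @param fps frames per second (positive).
#' @return object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, expression = "eye_cycle",
                           subject_id = "subject", fps = 30) {
  if (!is.list(frames) || !all(vapply(frames, inherits, TRUE, "landmark_set")))
    stop("frames must be a list of landmark_set objects")
  expression <- match.arg(expression, c("open_eye", "closed_eye",
                                        "bare_teeth", "bulge_mouth",
                                        "eye_cycle"))
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("fps must be a single positive number")
  if (length(frames) > 1L) {
    fi <- vapply(frames, function(f) f$frame_index, integer(1))
    if (any(diff(fi) <= 0L))
      stop("frame_index must be strictly increasing across frames")
  }
  structure(list(frames = frames, expression = expression,
                 subject_id = as.character(subject_id), fps = fps),
            class = "frame_sequence")
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' @export
print.frame_sequence <- function(x, ...) {
  cat("frame_sequence:", length(x$frames), "frames, expression",
      shQuote(x$expression), ", subject", shQuote(x$subject_id),
      ",", x$fps, "fps\n")
  invisible(x)
}

seq_points_array <- function(seq) {
  # frames x 68 x 2 array view, used internally
  vapply(seq$frames, function(f) f$points, matrix(0, 68, 2))
}

#' Read a landmark frame sequence
#'
#' Supported dialects:
#' \describe{
#'   \item{csv}{long form, one row per (frame, point), columns
#'     `frame,index,x,y` with 0-based `index`.}
#'   \item{json}{object with fields `expression`, `subject_id`, `fps` and
#'     `frames`, each frame holding `frame_index`, `source` and a 68 x 2
#'     `points` array.}
#'   \item{pts}{the standard `version:/n_points:/\{...\}` annotation layout;
#'     `path` may be a single `.pts` file (one frame) or a directory of
#'     `.pts` files taken in lexicographic order.}
#' }
#'
#' @param path file (or, for pts, directory) to read.
#' @param format `"csv"`, `"json"` or `"pts"`.
#' @param expression,subject_id,fps sequence metadata for formats that do
#'   not store it (csv, pts).
#' @return a [frame_sequence()].
#' @export
read_landmarks <- function(path, format = c("csv", "json", "pts"),
                           expression = "eye_cycle", subject_id = "subject",
                           fps = 30) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(format,
    csv = read_landmarks_csv(path, expression, subject_id, fps),
    json = read_landmarks_json(path),
    pts = read_landmarks_pts(path, expression, subject_id, fps))
}

read_landmarks_csv <- function(path, expression, subject_id, fps) {
  df <- utils::read.csv(path)
  need <- c("frame", "index", "x", "y")
  if (!all(need %in% names(df)))
    stop("landmark CSV must have columns frame,index,x,y; found: ",
         paste(names(df), collapse = ","))
  frames <- lapply(split(df, df$frame), function(d) {
    d <- d[order(d$index), ]
    if (nrow(d) != 68L || !identical(as.integer(d$index), 0:67))
      stop("frame ", d$frame[1], ": expected point indices 0..67, got ",
           nrow(d), " rows")
    landmark_set(cbind(d$x, d$y), frame_index = d$frame[1],
                 source = "annotated")
  })
  frames <- frames[order(vapply(frames, function(f) f$frame_index, 1L))]
  frame_sequence(frames, expression, subject_id, fps)
}

read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$frames)) stop("landmark JSON missing 'frames' field")
  fr <- obj$frames
  frames <- lapply(seq_len(nrow(fr)), function(i) {
    landmark_set(fr$points[[i]], frame_index = fr$frame_index[i],
                 source = fr$source[i])
  })
  frame_sequence(frames, obj$expression, obj$subject_id, obj$fps)
}

read_one_pts <- function(file, frame_index) {
  lines <- trimws(readLines(file, warn = FALSE))
  open <- match("{", lines)
  close <- match("}", lines)
  if (is.na(open) || is.na(close) || close <= open)
    stop("malformed pts file (missing { } block): ", file)
  np_line <- grep("^n_points:", lines[seq_len(open)], value = TRUE)
  if (length(np_line) == 1L) {
    np <- as.integer(sub("^n_points:\\s*", "", np_line))
    if (!is.na(np) && np != 68L)
      stop("pts file ", file, " declares n_points ", np, ", expected 68")
  }
  body <- lines[(open + 1L):(close - 1L)]
  body <- body[nzchar(body)]
  if (length(body) != 68L)
    stop("pts file ", file, " has ", length(body), " points, expected 68")
  coords <- do.call(rbind, lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(body[i], "\\s+")[[1]]))
    if (length(v) != 2L || any(is.na(v)))
      stop("pts file ", file, ": cannot parse point line ", i, ": ", body[i])
    v
  }))
  landmark_set(coords, frame_index = frame_index, source = "annotated")
}

read_landmarks_pts <- function(path, expression, subject_id, fps) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.pts$", full.names = TRUE))
    if (length(files) == 0L) stop("no .pts files in directory: ", path)
  } else files <- path
  frames <- lapply(seq_along(files),
                   function(i) read_one_pts(files[i], i - 1L))
  frame_sequence(frames, expression, subject_id, fps)
}

#' Write a landmark frame sequence
#'
#' Inverse of [read_landmarks()]; the round trip preserves coordinates to
#' at least 6 decimal places (csv/pts) or exactly (json).
#'
#' @param seq a [frame_sequence()].
#' @param path destination file; for pts, a directory (created if absent)
#'   receiving one `frame_NNNN.pts` file per frame.
#' @param format `"csv"`, `"json"` or `"pts"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(seq, path, format = c("csv", "json", "pts")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "frame_sequence"))
  switch(format,
    csv = {
      rows <- lapply(seq$frames, function(f)
        data.frame(frame = f$frame_index, index = 0:67,
                   x = f$points[, 1], y = f$points[, 2]))
      df <- if (length(rows)) do.call(rbind, rows) else
        data.frame(frame = integer(), index = integer(),
                   x = numeric(), y = numeric())
      utils::write.csv(df, path, row.names = FALSE)
    },
    json = {
      obj <- list(expression = seq$expression, subject_id = seq$subject_id,
                  fps = seq$fps,
                  frames = lapply(seq$frames, function(f)
                    list(frame_index = f$frame_index, source = f$source,
                         points = f$points)))
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    },
    pts = {
      if (!dir.exists(path)) dir.create(path, recursive = TRUE)
      for (f in seq$frames) {
        lines <- c("version: 1", "n_points: 68", "{",
                   sprintf("%.6f %.6f", f$points[, 1], f$points[, 2]), "}")
        writeLines(lines,
                   file.path(path, sprintf("frame_%04d.pts", f$frame_index)))
      }
    })
  invisible(path)
}
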