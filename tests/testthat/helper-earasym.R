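# Shared fixture builders; everything is generated in code.

# Template with selected 0-based indices overwritten; used to build exact
# hand-computable EAR / NME configurations.
face_with <- function(overrides) {
  p <- template_face()$points
  for (nm in names(overrides)) p[as.integer(nm) + 1L, ] <- overrides[[nm]]
  landmark_set(p)
}

# Left-eye configuration with prescribed lid distances / corner distance /
# amplification, everything else from the template.
eye_case_left <- function(v = 1, h = 2, amp = 1) {
  # corners (36, 39) h apart; lids (37,41) and (38,40) v apart vertically;
  # nose 27->33 length 40; brow point 19 placed amp * 40 from 33
  face_with(list(
    `36` = c(0, 0), `39` = c(h, 0),
    `37` = c(h / 4, -v / 2), `41` = c(h / 4, v / 2),
    `38` = c(3 * h / 4, -v / 2), `40` = c(3 * h / 4, v / 2),
    `27` = c(200, 0), `33` = c(200, 40),
    `19` = c(200 - amp * 40, 40)))
}

rotate_sequence <- function(seq, angle_deg, center = c(100, 100)) {
  frames <- lapply(seq$frames, function(f) {
    f$points <- earasym:::rotate_points(f$points, angle_deg * pi / 180,
                                        center)
    f
  })
  out <- seq
  out$frames <- frames
  out
}

# Small rendered dataset shared by detector tests (memoised per session)
small_face_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_face_dataset(14, size_px = 96, seed = 42)
    cache
  }
})
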