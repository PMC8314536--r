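# Small phantom specifications used across test files. Reduced image and
# slice counts keep the suite fast; the geometry is otherwise the default.

small_spec <- function(...) {
  args <- utils::modifyList(list(image_size = 64L, epi_radius = 20,
                                 endo_radius = 12, n_slices = 4L),
                            list(...))
  do.call(phantom_spec, args)
}

# A ring mask plus SI image with a rectangular warm patch, built directly
# (no phantom generator) for ROI-detection tests.
ring_fixture <- function(size = 61L, r_in = 8, r_out = 18) {
  ctr <- (size + 1) / 2
  rows <- row(matrix(0, size, size))
  cols <- col(matrix(0, size, size))
  r <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  mask <- r >= r_in & r <= r_out
  ang <- (atan2(ctr - rows, cols - ctr) * 180 / pi) %% 360
  list(mask = mask, angle = ang, rows = rows, cols = cols, center = ctr)
}
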