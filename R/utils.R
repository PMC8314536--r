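# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(expr)
}

#' Dice overlap coefficient
#'
#' Computes `2|A n B| / (|A| + |B|)` for two binary masks of identical shape.
#' Two empty masks are defined to have Dice 1 (identical).
#'
#' @param a,b Logical vectors, matrices or arrays of equal length.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' dice_coefficient(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
dice_coefficient <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) {
    stopf("dice_coefficient: masks differ in length (%d vs %d)", length(a), length(b))
  }
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' Regular polygon approximating a circle
#'
#' Vertices are returned in pixel coordinates (`x` = column, `y` = row,
#' 1-based pixel centers), counter-clockwise in display orientation.
#'
#' @param cx,cy Center, pixel coordinates (x = column, y = row).
#' @param radius Radius in pixels.
#' @param n_vertices Number of vertices.
#' @return A numeric matrix with columns `x` and `y`.
#' @export
circle_polygon <- function(cx, cy, radius, n_vertices = 128L) {
  if (radius <= 0) stopf("circle_polygon: radius must be positive")
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(x = cx + radius * cos(th), y = cy - radius * sin(th))
}

# Angle of pixels about a center, degrees in [0, 360).
# Convention (documented in ?aha17_segments): mathematical angle in display
# orientation, i.e. atan2(center_row - row, col - center_col); image-up is 90
# degrees and angles increase counter-clockwise on the displayed image.
pixel_angles <- function(rows, cols, center_row, center_col) {
  (atan2(center_row - rows, cols - center_col) * 180 / pi) %% 360
}

as_pixels <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 2L) stopf("pixels must be a two-column (row, col) matrix")
  storage.mode(pixels) <- "integer"
  colnames(pixels) <- c("row", "col")
  pixels
}

pixels_to_index <- function(pixels, dim) {
  (pixels[, 2L] - 1L) * dim[1L] + pixels[, 1L]
}
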