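# ECV map computation from pre/post-contrast T1 and hematocrit.

#' Compute a per-pixel ECV map
#'
#' Extracellular volume fraction from pre- and post-contrast T1 of myocardium
#' and blood pool, scaled by one minus hematocrit:
#' \deqn{ECV = (1 - Hct)\,\frac{1/T1_{myo,post} - 1/T1_{myo,pre}}
#'                             {1/T1_{blood,post} - 1/T1_{blood,pre}}}
#' Computation is carried out in fractions and reported in percent, the unit
#' used throughout the package. Pixels where either myocardial T1 map is
#' undefined are excluded from the valid mask. Non-physical values (noise can
#' push ECV below 0 or above 100) are retained but flagged rather than
#' clipped, so ROI means are not biased.
#'
#' @param pair A [t1_pair()] object.
#' @return An [ecv_map()] with ECV in percent.
#' @export
#' @examples
#' pre <- matrix(1200, 2, 2); post <- matrix(400, 2, 2)
#' pair <- t1_pair(pre, post, 1800, 300, hematocrit = 0.40)
#' compute_ecv(pair)$ecv[1, 1]  # 36%
compute_ecv <- function(pair) {
  if (!inherits(pair, "t1_pair")) stopf("compute_ecv: pair must be a t1_pair")
  d_r1_blood <- 1 / pair$t1_blood_post - 1 / pair$t1_blood_pre
  if (d_r1_blood == 0) {
    stopf("compute_ecv: degenerate input, blood-pool R1 change is zero")
  }
  d_r1_myo <- 1 / pair$t1_myo_post - 1 / pair$t1_myo_pre
  frac <- (1 - pair$hematocrit) * d_r1_myo / d_r1_blood
  valid <- is.finite(pair$t1_myo_pre) & is.finite(pair$t1_myo_post)
  ecv <- 100 * frac
  ecv[!valid] <- NA_real_
  ecv_map(ecv, valid)
}

#' Mean map value over a region of interest
#'
#' Samples an ECV map (or any per-pixel map such as native T1) at the pixels
#' of an ROI and returns the arithmetic mean. Pixels of the ROI falling
#' outside the map's valid mask are excluded and reported via the
#' `n_excluded` attribute.
#'
#' @param map2d An [ecv_map()] or a plain numeric matrix.
#' @param roi A [roi_ref()].
#' @return Scalar mean over the (valid) ROI pixels.
#' @export
sample_at_roi <- function(map2d, roi) {
  if (!inherits(roi, "roi_ref")) stopf("sample_at_roi: roi must be a roi_ref")
  if (inherits(map2d, "ecv_map")) {
    values <- map2d$ecv
    valid <- map2d$valid_mask
  } else if (is.matrix(map2d)) {
    values <- map2d
    valid <- is.finite(map2d)
  } else {
    stopf("sample_at_roi: map2d must be an ecv_map or a matrix")
  }
  if (!nrow(roi$pixels)) stopf("sample_at_roi: empty ROI")
  if (any(roi$pixels[, 1L] < 1L | roi$pixels[, 1L] > nrow(values) |
            roi$pixels[, 2L] < 1L | roi$pixels[, 2L] > ncol(values))) {
    stopf("sample_at_roi: ROI pixel outside the map grid")
  }
  idx <- pixels_to_index(roi$pixels, dim(values))
  ok <- valid[idx]
  if (!any(ok)) stopf("sample_at_roi: no ROI pixel falls inside the valid mask")
  out <- mean(values[idx[ok]])
  n_excl <- sum(!ok)
  if (n_excl > 0) {
    warnf("sample_at_roi: %d ROI pixel(s) outside the valid mask excluded", n_excl)
  }
  structure(out, n_excluded = n_excl)
}
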