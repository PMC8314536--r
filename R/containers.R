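# Lightweight S3 containers shared across the analysis modules.

#' Short-axis LGE image stack
#'
#' Container for a stack of short-axis late gadolinium enhancement (LGE)
#' signal-intensity images together with its geometry. Slices are ordered
#' base to apex; the mid-LV slice is the one matched to the T1/ECV
#' acquisition.
#'
#' @param data Numeric 3-D array `[row, col, slice]` of signal intensities
#'   (PSIR images are signed; values may be negative).
#' @param pixel_spacing In-plane pixel spacing, mm.
#' @param slice_thickness Slice thickness, mm.
#' @param mid_slice Index of the mid-LV slice. Defaults to
#'   `floor(n_slices / 2) + 1`.
#' @return An object of class `lge_stack`.
#' @export
lge_stack <- function(data, pixel_spacing, slice_thickness,
                      mid_slice = floor(dim(data)[3] / 2) + 1L) {
  data <- as.array(data)
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3L) stopf("lge_stack: data must be a 3-D array")
  if (pixel_spacing <= 0 || slice_thickness <= 0) {
    stopf("lge_stack: pixel_spacing and slice_thickness must be positive")
  }
  mid_slice <- as.integer(mid_slice)
  if (mid_slice < 1L || mid_slice > dim(data)[3]) {
    stopf("lge_stack: mid_slice %d outside 1..%d", mid_slice, dim(data)[3])
  }
  structure(
    list(data = data, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness, mid_slice = mid_slice),
    class = "lge_stack"
  )
}

#' @export
print.lge_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lge_stack> %d x %d px, %d slices (mid %d), %.2f mm px, %.1f mm thick\n",
              d[1], d[2], d[3], x$mid_slice, x$pixel_spacing, x$slice_thickness))
  invisible(x)
}

#' Per-slice myocardial ring masks
#'
#' @param masks List of logical matrices, one per slice (base to apex).
#' @param pixel_spacing In-plane pixel spacing, mm.
#' @param slice_thickness Slice thickness, mm.
#' @return An object of class `myo_mask`.
#' @export
myo_mask <- function(masks, pixel_spacing, slice_thickness) {
  if (!is.list(masks) || !length(masks)) stopf("myo_mask: masks must be a non-empty list")
  masks <- lapply(masks, function(m) {
    if (!is.matrix(m)) stopf("myo_mask: each slice mask must be a matrix")
    storage.mode(m) <- "logical"
    m
  })
  if (pixel_spacing <= 0 || slice_thickness <= 0) {
    stopf("myo_mask: geometry must be positive")
  }
  structure(list(masks = masks, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness),
            class = "myo_mask")
}

#' Region-of-interest reference
#'
#' A labeled subset of myocardial pixels on one slice, e.g. the automatically
#' detected remote-myocardium or high-signal-intensity region.
#'
#' @param slice_index Slice the ROI lives on.
#' @param pixels Integer matrix with columns `row`, `col` (1-based).
#' @param label One of `"remote"` or `"high-SI"`.
#' @return An object of class `roi_ref`.
#' @export
roi_ref <- function(slice_index, pixels, label = c("remote", "high-SI")) {
  label <- match.arg(label)
  pixels <- as_pixels(pixels)
  if (!nrow(pixels)) stopf("roi_ref: ROI must contain at least one pixel")
  structure(list(slice_index = as.integer(slice_index), pixels = pixels,
                 label = label),
            class = "roi_ref")
}

#' @export
print.roi_ref <- function(x, ...) {
  cat(sprintf("<roi_ref> %s, slice %d, %d px\n", x$label, x$slice_index, nrow(x$pixels)))
  invisible(x)
}

#' Pre/post-contrast T1 maps with blood-pool values and hematocrit
#'
#' Myocardial T1 is per-pixel (mid-LV slice grid, `NA` outside the
#' myocardium); blood-pool T1 values are scalars (ROI means supplied
#' upstream), following standard single-slice ECV practice.
#'
#' @param t1_myo_pre,t1_myo_post Numeric matrices of myocardial T1, ms.
#' @param t1_blood_pre,t1_blood_post Scalar blood-pool T1, ms.
#' @param hematocrit Hematocrit as a fraction in (0, 1).
#' @return An object of class `t1_pair`.
#' @export
t1_pair <- function(t1_myo_pre, t1_myo_post, t1_blood_pre, t1_blood_post,
                    hematocrit) {
  if (!is.matrix(t1_myo_pre) || !is.matrix(t1_myo_post) ||
      !all(dim(t1_myo_pre) == dim(t1_myo_post))) {
    stopf("t1_pair: T1 maps must be matrices of identical dimension")
  }
  if (any(t1_myo_pre <= 0, na.rm = TRUE) || any(t1_myo_post <= 0, na.rm = TRUE)) {
    stopf("t1_pair: T1 values must be positive where defined")
  }
  if (t1_blood_pre <= 0 || t1_blood_post <= 0) {
    stopf("t1_pair: blood T1 values must be positive")
  }
  if (!is.numeric(hematocrit) || hematocrit <= 0 || hematocrit >= 1) {
    stopf("t1_pair: hematocrit must lie strictly between 0 and 1")
  }
  structure(list(t1_myo_pre = t1_myo_pre, t1_myo_post = t1_myo_post,
                 t1_blood_pre = t1_blood_pre, t1_blood_post = t1_blood_post,
                 hematocrit = hematocrit),
            class = "t1_pair")
}

#' Per-pixel ECV map
#'
#' @param ecv Numeric matrix of extracellular volume fraction in percent.
#' @param valid_mask Logical matrix marking pixels where both T1 maps were
#'   defined. Non-physical values (outside 0--100) are retained but flagged
#'   in the `out_of_range` attribute; thresholding ignores the flag so that
#'   noisy pixels are not silently clipped.
#' @return An object of class `ecv_map`.
#' @export
ecv_map <- function(ecv, valid_mask = !is.na(ecv)) {
  if (!is.matrix(ecv)) stopf("ecv_map: ecv must be a matrix")
  if (!all(dim(valid_mask) == dim(ecv))) stopf("ecv_map: valid_mask dimension mismatch")
  storage.mode(valid_mask) <- "logical"
  if (any(!is.finite(ecv[valid_mask]))) {
    stopf("ecv_map: ECV must be finite on the valid mask")
  }
  oor <- valid_mask & (ecv < 0 | ecv > 100)
  structure(list(ecv = ecv, valid_mask = valid_mask),
            out_of_range = oor, class = "ecv_map")
}

#' @export
print.ecv_map <- function(x, ...) {
  v <- x$ecv[x$valid_mask]
  cat(sprintf("<ecv_map> %d x %d px, %d valid; ECV %% median %.1f [%.1f, %.1f]\n",
              nrow(x$ecv), ncol(x$ecv), sum(x$valid_mask),
              stats::median(v), min(v), max(v)))
  n_oor <- sum(attr(x, "out_of_range"))
  if (n_oor > 0) cat(sprintf("  %d pixel(s) outside 0-100%% (flagged, not clipped)\n", n_oor))
  invisible(x)
}

#' Threshold selection record
#'
#' @param method `"nsd"` or `"fwhm"`.
#' @param n SD multiple (n-SD method only, otherwise `NA`).
#' @param absolute_threshold Threshold in signal-intensity units.
#' @param scenario `"scar"`, `"non-scar"` or `"n/a"`.
#' @return An object of class `threshold_selection`.
#' @export
threshold_selection <- function(method = c("nsd", "fwhm"), n = NA_real_,
                                absolute_threshold, scenario = "n/a") {
  method <- match.arg(method)
  scenario <- match.arg(scenario, c("scar", "non-scar", "n/a"))
  structure(list(method = method, n = n,
                 absolute_threshold = absolute_threshold, scenario = scenario),
            class = "threshold_selection")
}

#' @export
print.threshold_selection <- function(x, ...) {
  lab <- if (x$method == "nsd") sprintf("%.1f-SD", x$n) else "FWHM"
  cat(sprintf("<threshold_selection> %s, absolute threshold %.2f SI (scenario: %s)\n",
              lab, x$absolute_threshold, x$scenario))
  invisible(x)
}
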