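# ECV-guided LGE analysis: apply the ECV criteria at the high-SI ROI of the
# mid-LV slice, select the per-case optimal n-SD threshold (scenario
# dependent), propagate it across the stack and report scar burden.

#' Configuration for ECV-guided LGE analysis
#'
#' @param ecv_cutoff ECV cutoff in percent separating scar from non-scar at
#'   the high-SI ROI (default 31.5).
#' @param n_grid Ordered grid of candidate n-SD multiples (default 1 to 20
#'   in steps of 0.5, covering the 3-18 SD range seen in practice with
#'   headroom).
#' @param nonscar_tolerance_px In the non-scar scenario, the number of
#'   high-SI ROI pixels the chosen threshold may still highlight (default 0:
#'   "does not highlight" taken literally).
#' @param agreement_metric Overlap metric for the scar-scenario threshold
#'   search; only `"dice"` is currently implemented.
#' @param nt1_cutoff Native-T1 cutoff in ms for the alternative
#'   [classify_roi()] criterion (default 1317).
#' @return Object of class `ecv_guided_config`.
#' @export
ecv_guided_config <- function(ecv_cutoff = 31.5, n_grid = seq(1, 20, by = 0.5),
                              nonscar_tolerance_px = 0L,
                              agreement_metric = "dice", nt1_cutoff = 1317) {
  if (ecv_cutoff <= 0 || ecv_cutoff >= 100) stopf("ecv_cutoff must be in (0, 100)")
  if (!length(n_grid) || any(diff(n_grid) <= 0)) {
    stopf("n_grid must be non-empty and strictly increasing")
  }
  if (nonscar_tolerance_px < 0) stopf("nonscar_tolerance_px must be >= 0")
  agreement_metric <- match.arg(agreement_metric, "dice")
  structure(list(ecv_cutoff = ecv_cutoff, n_grid = n_grid,
                 nonscar_tolerance_px = as.integer(nonscar_tolerance_px),
                 agreement_metric = agreement_metric, nt1_cutoff = nt1_cutoff),
            class = "ecv_guided_config")
}

#' Classify the high-SI ROI as scar or non-scar
#'
#' Scar when the ROI value is at or above the cutoff (boundary inclusive).
#' The default criterion compares the ROI-mean ECV against `ecv_cutoff`;
#' `criterion = "nt1"` compares a native-T1 ROI value (ms) against
#' `nt1_cutoff` as the alternative decision rule.
#'
#' @param roi_value ROI-mean ECV (percent) or native T1 (ms).
#' @param config An [ecv_guided_config()].
#' @param criterion `"ecv"` (default) or `"nt1"`.
#' @return `"scar"` or `"non-scar"`.
#' @export
classify_roi <- function(roi_value, config = ecv_guided_config(),
                         criterion = c("ecv", "nt1")) {
  criterion <- match.arg(criterion)
  if (!is.finite(roi_value)) stopf("classify_roi: roi_value must be finite")
  cutoff <- if (criterion == "ecv") config$ecv_cutoff else config$nt1_cutoff
  if (roi_value >= cutoff) "scar" else "non-scar"
}

#' Optimal n-SD threshold in the scar scenario
#'
#' The reference workflow selects n visually so that the thresholded LGE
#' area matches the scar extent seen on the ECV map; here that visual step
#' is automated as Dice maximization of the n-SD mask against the mask of
#' myocardial pixels with ECV at or above the cutoff. Ties are broken toward
#' the larger n (the more conservative, smaller scar estimate).
#'
#' @param mid_lge Mid-slice signal-intensity matrix.
#' @param myo_mid Mid-slice myocardial mask.
#' @param remote A [remote_stats()] object.
#' @param ecv_scar_mask Logical matrix of myocardial pixels with ECV >=
#'   cutoff (non-empty).
#' @param config An [ecv_guided_config()].
#' @return List with `n` (selected multiple), `dice` (achieved maximum) and
#'   `degenerate` (`TRUE` when every candidate mask was empty, in which case
#'   the smallest grid n is returned with a warning).
#' @export
select_n_scar <- function(mid_lge, myo_mid, remote, ecv_scar_mask, config) {
  if (!any(ecv_scar_mask)) stopf("select_n_scar: ECV scar mask is empty")
  best_n <- NA_real_
  best_d <- -Inf
  any_px <- FALSE
  for (n in config$n_grid) {
    m <- nsd_mask(mid_lge, myo_mid, remote, n)$mask
    if (any(m)) any_px <- TRUE
    d <- dice_coefficient(m, ecv_scar_mask)
    if (d >= best_d) {       # >=: ties resolve toward larger n
      best_d <- d
      best_n <- n
    }
  }
  if (!any_px) {
    warnf("select_n_scar: no candidate threshold highlighted any pixel; returning the smallest n")
    return(list(n = config$n_grid[1L], dice = 0, degenerate = TRUE))
  }
  list(n = best_n, dice = best_d, degenerate = FALSE)
}

#' Closest non-highlighting n-SD threshold in the non-scar scenario
#'
#' The smallest n on the grid whose mask highlights at most
#' `nonscar_tolerance_px` pixels of the high-SI ROI ("the closest threshold
#' that does not highlight the high-SI ROI"). When no grid value suppresses
#' the ROI, the largest grid n is returned with a warning.
#'
#' @param mid_lge Mid-slice signal-intensity matrix.
#' @param myo_mid Mid-slice myocardial mask.
#' @param remote A [remote_stats()] object.
#' @param highsi The high-SI [roi_ref()].
#' @param config An [ecv_guided_config()].
#' @return List with `n` and `degenerate`.
#' @export
select_n_nonscar <- function(mid_lge, myo_mid, remote, highsi, config) {
  idx <- pixels_to_index(highsi$pixels, dim(mid_lge))
  for (n in config$n_grid) {
    m <- nsd_mask(mid_lge, myo_mid, remote, n)$mask
    if (sum(m[idx]) <= config$nonscar_tolerance_px) {
      return(list(n = n, degenerate = FALSE))
    }
  }
  warnf("select_n_nonscar: no grid threshold suppresses the high-SI ROI; returning the largest n")
  list(n = config$n_grid[length(config$n_grid)], degenerate = TRUE)
}

#' Run the full ECV-guided LGE analysis
#'
#' Pipeline: rasterize myocardial masks from the contours; auto-detect the
#' remote and high-SI ROIs on the mid-LV slice; sample the ECV map at the
#' high-SI ROI; classify scar/non-scar against the ECV cutoff; select the
#' per-case n-SD threshold ([select_n_scar()] in the scar scenario,
#' [select_n_nonscar()] otherwise); propagate the threshold to all slices;
#' filter small components; and compute the scar mass/percent report.
#'
#' A mid-slice non-scar classification can still yield scar on other slices
#' after propagation, when lesions elsewhere in the stack exceed the chosen
#' threshold.
#'
#' @param stack An [lge_stack()].
#' @param contours Per-slice list of `list(epi = , endo = )` polygon
#'   matrices.
#' @param t1_or_ecv An [ecv_map()] for the mid-LV slice, or a [t1_pair()]
#'   from which one is computed. Missing mid-slice ECV data is a hard error.
#' @param config An [ecv_guided_config()].
#' @param density Myocardial density, g/mL.
#' @param min_component_px Small-component filter size, see
#'   [filter_components()].
#' @param per_slice_remote Propagation mode, see [propagate_threshold()].
#' @param n_sectors,arc_width ROI detection parameters.
#' @return Object of class `ecv_guided_report`: `roi_ecv`, `scenario`,
#'   `selected_n`, `mid_slice_dice` (scar scenario only), `scar`
#'   ([scar_result()]), `selection`, `remote`, `rois`, `config`.
#' @export
run_ecv_guided <- function(stack, contours, t1_or_ecv,
                           config = ecv_guided_config(), density = 1.05,
                           min_component_px = 5L, per_slice_remote = TRUE,
                           n_sectors = 60L, arc_width = 5L) {
  if (!inherits(stack, "lge_stack")) stopf("run_ecv_guided: stack must be an lge_stack")
  dims <- dim(stack$data)
  if (length(contours) != dims[3]) {
    stopf("run_ecv_guided: contours must be supplied for all %d slices", dims[3])
  }
  ecv <- if (inherits(t1_or_ecv, "t1_pair")) compute_ecv(t1_or_ecv) else t1_or_ecv
  if (!inherits(ecv, "ecv_map")) {
    stopf("run_ecv_guided: t1_or_ecv must be an ecv_map or a t1_pair")
  }
  if (!any(ecv$valid_mask)) {
    stopf("run_ecv_guided: no valid ECV data for the mid-LV slice")
  }
  myo <- myo_from_contours(contours, dims[1:2], stack$pixel_spacing,
                           stack$slice_thickness)
  mid <- stack$mid_slice
  mid_lge <- stack$data[, , mid]
  myo_mid <- myo$masks[[mid]]
  rois <- auto_detect_rois(mid_lge, myo_mid, n_sectors, arc_width,
                           slice_index = mid)
  roi_ecv <- as.numeric(sample_at_roi(ecv, rois$highsi))
  scenario <- classify_roi(roi_ecv, config)
  remote <- remote_stats(mid_lge, rois$remote)
  if (scenario == "scar") {
    ecv_scar <- myo_mid & ecv$valid_mask & !is.na(ecv$ecv) &
      (ecv$ecv >= config$ecv_cutoff)
    sel <- select_n_scar(mid_lge, myo_mid, remote, ecv_scar, config)
    selected_n <- sel$n
    mid_dice <- sel$dice
  } else {
    sel <- select_n_nonscar(mid_lge, myo_mid, remote, rois$highsi, config)
    selected_n <- sel$n
    mid_dice <- NA_real_
  }
  selection <- threshold_selection(
    "nsd", n = selected_n,
    absolute_threshold = remote$mean_si + selected_n * remote$sd_si,
    scenario = scenario
  )
  masks <- propagate_threshold(stack, myo, selection, per_slice_remote,
                               n_sectors, arc_width)
  masks <- filter_components(masks, min_component_px)
  segments <- if (length(myo$masks) >= 3L) aha17_segments(myo) else NULL
  scar <- scar_result(masks, myo, segments, density)
  structure(list(roi_ecv = roi_ecv, scenario = scenario,
                 selected_n = selected_n, mid_slice_dice = mid_dice,
                 scar = scar, selection = selection, remote = remote,
                 rois = rois, config = config),
            class = "ecv_guided_report")
}

#' @export
print.ecv_guided_report <- function(x, ...) {
  cat(sprintf("<ecv_guided_report> high-SI ROI ECV %.1f%% -> %s (cutoff %.1f%%)\n",
              x$roi_ecv, x$scenario, x$config$ecv_cutoff))
  cat(sprintf("  selected threshold: %.1f-SD", x$selected_n))
  if (!is.na(x$mid_slice_dice)) cat(sprintf(" (mid-slice Dice %.3f)", x$mid_slice_dice))
  cat("\n")
  cat(sprintf("  global scar: %.2f g / %.2f g LV = %.2f%%\n",
              x$scar$scar_mass_g, x$scar$lv_mass_g, x$scar$scar_percent))
  invisible(x)
}
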