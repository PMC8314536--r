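# Thresholding primitives (n-SD, FWHM), threshold propagation, small-component
# filtering, and scar mass / percent / segmental reporting.
#
# Inequality conventions, fixed for reproducibility: n-SD masks use a strict
# ">" (a pixel exactly at mean + n*SD is not scar); FWHM masks use ">=".

#' Remote-myocardium signal statistics
#'
#' Mean and sample standard deviation (n-1 denominator; reference ROIs are
#' small) of the signal intensity over a remote-myocardium ROI.
#'
#' @param lge_slice Signal-intensity matrix.
#' @param remote A [roi_ref()] with at least 2 pixels.
#' @return Object of class `remote_stats`: `mean_si`, `sd_si`, `n_pixels`.
#' @export
remote_stats <- function(lge_slice, remote) {
  if (!inherits(remote, "roi_ref")) stopf("remote_stats: remote must be a roi_ref")
  if (nrow(remote$pixels) < 2L) stopf("remote_stats: need at least 2 ROI pixels")
  si <- lge_slice[pixels_to_index(remote$pixels, dim(lge_slice))]
  structure(list(mean_si = mean(si), sd_si = stats::sd(si),
                 n_pixels = length(si)),
            class = "remote_stats")
}

#' n-SD threshold mask
#'
#' Scar candidate pixels are myocardial pixels with SI strictly above
#' `mean + n * SD` of the remote myocardium.
#'
#' @param lge_slice Signal-intensity matrix.
#' @param myo_slice Logical myocardial mask.
#' @param stats A [remote_stats()] object with `sd_si > 0`.
#' @param n SD multiple, `n >= 0`.
#' @return List with `mask` (logical matrix) and `selection`
#'   ([threshold_selection()]).
#' @export
nsd_mask <- function(lge_slice, myo_slice, stats, n) {
  if (n < 0) stopf("nsd_mask: n must be non-negative")
  if (!inherits(stats, "remote_stats")) stopf("nsd_mask: stats must be remote_stats")
  if (stats$sd_si <= 0) {
    stopf("nsd_mask: degenerate threshold, remote SD is zero")
  }
  thr <- stats$mean_si + n * stats$sd_si
  list(mask = myo_slice & (lge_slice > thr),
       selection = threshold_selection("nsd", n = n, absolute_threshold = thr))
}

#' Full-width half-maximum threshold mask
#'
#' `S_max` is the maximum SI within the seed ROI (typically the auto-detected
#' high-SI region). The default threshold is `S_max / 2`; with
#' `baseline_corrected = TRUE` the half-maximum is measured above the remote
#' mean, `threshold = mu_remote + 0.5 * (S_max - mu_remote)`, which is the
#' appropriate form when the remote signal has a nonzero offset (as on the
#' signed PSIR scale). Scar pixels are myocardial pixels with SI at or above
#' the threshold.
#'
#' @param lge_slice Signal-intensity matrix.
#' @param myo_slice Logical myocardial mask.
#' @param seed_roi A [roi_ref()] marking the hyperenhanced region.
#' @param baseline_corrected Use the remote-baseline-corrected variant.
#' @param remote A [remote_stats()] object; required when
#'   `baseline_corrected = TRUE`.
#' @return List with `mask` and `selection`.
#' @export
fwhm_mask <- function(lge_slice, myo_slice, seed_roi, baseline_corrected = FALSE,
                      remote = NULL) {
  if (!inherits(seed_roi, "roi_ref")) stopf("fwhm_mask: seed_roi must be a roi_ref")
  if (!nrow(seed_roi$pixels)) stopf("fwhm_mask: empty seed ROI")
  s_max <- max(lge_slice[pixels_to_index(seed_roi$pixels, dim(lge_slice))])
  if (baseline_corrected) {
    if (is.null(remote)) stopf("fwhm_mask: baseline correction needs remote stats")
    if (s_max <= remote$mean_si) {
      stopf("fwhm_mask: seed maximum does not exceed the remote mean")
    }
    thr <- remote$mean_si + 0.5 * (s_max - remote$mean_si)
  } else {
    thr <- s_max / 2
  }
  list(mask = myo_slice & (lge_slice >= thr),
       selection = threshold_selection("fwhm", absolute_threshold = thr))
}

#' Propagate a mid-slice threshold selection across the stack
#'
#' For an n-SD selection with `per_slice_remote = TRUE` (the default), the
#' remote ROI is re-detected on every slice and the same `n` is applied to
#' that slice's remote statistics; this makes the resulting scar masks
#' invariant to per-slice rescaling of the SI scale (PSIR scaling varies by
#' slice). With `per_slice_remote = FALSE`, and always for FWHM selections,
#' the mid-slice absolute threshold is applied to every slice. Slices where
#' no usable remote ROI can be found (e.g. a degenerate SD) fall back to the
#' absolute threshold with a warning.
#'
#' @param stack An [lge_stack()].
#' @param myo A [myo_mask()] with one mask per slice.
#' @param selection A [threshold_selection()] derived from the mid slice.
#' @param per_slice_remote Re-estimate remote statistics per slice (n-SD only).
#' @param n_sectors,arc_width ROI-detection parameters, see
#'   [auto_detect_rois()].
#' @return List of per-slice logical scar masks.
#' @export
propagate_threshold <- function(stack, myo, selection, per_slice_remote = TRUE,
                                n_sectors = 60L, arc_width = 5L) {
  if (!inherits(selection, "threshold_selection")) {
    stopf("propagate_threshold: selection must be a threshold_selection")
  }
  n_slices <- dim(stack$data)[3]
  lapply(seq_len(n_slices), function(s) {
    sl <- stack$data[, , s]
    mm <- myo$masks[[s]]
    if (selection$method == "nsd" && per_slice_remote) {
      st <- tryCatch({
        rois <- auto_detect_rois(sl, mm, n_sectors, arc_width, slice_index = s)
        remote_stats(sl, rois$remote)
      }, error = function(e) NULL)
      if (is.null(st) || !is.finite(st$sd_si) || st$sd_si <= 0) {
        warnf("propagate_threshold: slice %d has no usable remote ROI; falling back to the absolute threshold", s)
        mm & (sl > selection$absolute_threshold)
      } else {
        mm & (sl > st$mean_si + selection$n * st$sd_si)
      }
    } else if (selection$method == "nsd") {
      mm & (sl > selection$absolute_threshold)
    } else {
      mm & (sl >= selection$absolute_threshold)
    }
  })
}

# Connected-component labeling on a binary matrix (breadth-first search).
# Returns an integer matrix; 0 = background, components numbered from 1 in
# raster order of their first pixel.
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  nr <- nrow(mask)
  nc <- ncol(mask)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  }
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  current <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    current <- current + 1L
    queue <- integer(64L)
    queue[1L] <- start
    lab[start] <- current
    head_i <- 1L
    tail_i <- 1L
    while (head_i <= tail_i) {
      j <- queue[head_i]
      head_i <- head_i + 1L
      r0 <- ((j - 1L) %% nr) + 1L
      c0 <- ((j - 1L) %/% nr) + 1L
      for (k in seq_along(dr)) {
        r <- r0 + dr[k]
        cc <- c0 + dc[k]
        if (r < 1L || r > nr || cc < 1L || cc > nc) next
        jj <- (cc - 1L) * nr + r
        if (mask[jj] && lab[jj] == 0L) {
          lab[jj] <- current
          tail_i <- tail_i + 1L
          if (tail_i > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[tail_i] <- jj
        }
      }
    }
  }
  lab
}

#' Remove small in-slice connected components
#'
#' Automated surrogate for manual erasure of acquisition-related artifacts:
#' connected components (within each slice) smaller than `min_component_px`
#' pixels are dropped. Idempotent; `min_component_px = 0` is the identity.
#'
#' @param masks A logical matrix or a list of per-slice logical matrices.
#' @param min_component_px Minimum component size in pixels (default 5,
#'   a typical noise-speckle suppression level; the reference workflow's
#'   erasure was manual, so this is configurable).
#' @param connectivity Pixel connectivity, 4 or 8 (default 8).
#' @return Masks of the same shape as the input.
#' @export
filter_components <- function(masks, min_component_px = 5L, connectivity = 8L) {
  if (min_component_px < 0) stopf("filter_components: min_component_px must be >= 0")
  one <- function(m) {
    if (min_component_px == 0L || !any(m)) return(m)
    lab <- label_components(m, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_component_px)
    matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (is.list(masks)) lapply(masks, one) else one(masks)
}

#' Scar mass, global percent and per-segment percent
#'
#' `scar mass = scar pixels x pixel volume x density`;
#' `scar percent = 100 * scar mass / LV mass`. The per-segment percent uses
#' pixel counts within the segment as the denominator:
#' `100 * scar pixels in segment / myocardial pixels in segment`.
#'
#' @param masks List of per-slice logical scar masks (subsets of the
#'   myocardium).
#' @param myo A [myo_mask()].
#' @param segments Optional [aha17_segments()] labels for the segmental
#'   report.
#' @param density Myocardial density, g/mL.
#' @return Object of class `scar_result` with `scar_mass_g`, `lv_mass_g`,
#'   `scar_percent`, `per_slice_px`, and (when segments are given)
#'   `per_segment_percent` (named by AHA segment number).
#' @export
scar_result <- function(masks, myo, segments = NULL, density = 1.05) {
  if (!is.list(masks) || length(masks) != length(myo$masks)) {
    stopf("scar_result: masks must be a per-slice list matching the myocardium")
  }
  for (s in seq_along(masks)) {
    if (any(masks[[s]] & !myo$masks[[s]])) {
      stopf("scar_result: scar mask extends outside the myocardium on slice %d", s)
    }
  }
  px_vol_ml <- myo$pixel_spacing^2 * myo$slice_thickness / 1000
  per_slice_px <- vapply(masks, sum, numeric(1))
  scar_mass <- sum(per_slice_px) * px_vol_ml * density
  lv <- lv_mass(myo, density)
  pct <- if (lv > 0) 100 * scar_mass / lv else 0
  per_segment <- NULL
  if (!is.null(segments)) {
    seg_ids <- sort(unique(unlist(lapply(segments$labels, function(l) l[!is.na(l)]))))
    scar_px <- myo_px <- stats::setNames(numeric(length(seg_ids)), seg_ids)
    for (s in seq_along(masks)) {
      l <- segments$labels[[s]]
      for (id in seg_ids) {
        sel <- !is.na(l) & l == id
        myo_px[as.character(id)] <- myo_px[as.character(id)] + sum(sel & myo$masks[[s]])
        scar_px[as.character(id)] <- scar_px[as.character(id)] + sum(sel & masks[[s]])
      }
    }
    per_segment <- ifelse(myo_px > 0, 100 * scar_px / myo_px, NA_real_)
  }
  structure(list(masks = masks, scar_mass_g = scar_mass, lv_mass_g = lv,
                 scar_percent = pct, per_slice_px = per_slice_px,
                 per_segment_percent = per_segment, density = density),
            class = "scar_result")
}

#' @export
print.scar_result <- function(x, ...) {
  cat(sprintf("<scar_result> scar %.2f g / LV %.2f g = %.2f%%\n",
              x$scar_mass_g, x$lv_mass_g, x$scar_percent))
  if (!is.null(x$per_segment_percent)) {
    nz <- x$per_segment_percent[!is.na(x$per_segment_percent) & x$per_segment_percent > 0]
    if (length(nz)) {
      cat("  segments with scar:",
          paste(sprintf("%s: %.1f%%", names(nz), nz), collapse = ", "), "\n")
    } else cat("  no segmental scar\n")
  }
  invisible(x)
}
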