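# Myocardial ring masks from contours, automatic remote / high-SI ROI
# detection, AHA 17-segment labeling, and LV mass.
#
# Coordinate conventions (fixed for reproducibility):
#   * pixels are addressed (row, col), 1-based, following R matrices;
#   * polygon vertices use pixel coordinates x = column, y = row;
#   * a pixel belongs to a region when its center lies inside the polygon
#     (boundary inclusive for the epicardium, exclusive for the endocardial
#     hole);
#   * angles about the ring centroid are measured counter-clockwise in
#     display orientation with image-up at 90 degrees (see pixel_angles).

#' Rasterize a myocardial ring from epi/endocardial contours
#'
#' A pixel is part of the ring when its center lies inside the epicardial
#' polygon and outside the endocardial polygon.
#'
#' @param epi,endo Polygon vertex matrices with columns `x` (column) and `y`
#'   (row), at least 3 vertices, non-self-intersecting, `endo` inside `epi`.
#' @param dim Image dimension `c(nrow, ncol)`.
#' @param on_empty What to do when the rasterized ring is empty: `"warn"`
#'   (default, returns the empty mask) or `"error"`.
#' @return Logical matrix of dimension `dim`.
#' @export
ring_mask_from_contours <- function(epi, endo, dim, on_empty = c("warn", "error")) {
  on_empty <- match.arg(on_empty)
  epi <- as.matrix(epi)
  endo <- as.matrix(endo)
  if (nrow(epi) < 3L || nrow(endo) < 3L) {
    stopf("ring_mask_from_contours: polygons need at least 3 vertices")
  }
  inside <- pracma::inpolygon(endo[, 1L], endo[, 2L], epi[, 1L], epi[, 2L],
                              boundary = TRUE)
  if (!all(inside)) {
    stopf("ring_mask_from_contours: endocardial contour is not contained in the epicardial contour")
  }
  nr <- dim[1L]; nc <- dim[2L]
  px_col <- rep(seq_len(nc), each = nr)
  px_row <- rep(seq_len(nr), times = nc)
  in_epi <- pracma::inpolygon(px_col, px_row, epi[, 1L], epi[, 2L], boundary = TRUE)
  in_endo <- pracma::inpolygon(px_col, px_row, endo[, 1L], endo[, 2L], boundary = TRUE)
  mask <- matrix(in_epi & !in_endo, nr, nc)
  if (!any(mask)) {
    msg <- "ring_mask_from_contours: rasterized ring is empty"
    if (on_empty == "error") stopf(msg) else warnf(msg)
  }
  mask
}

# Build a myo_mask from a per-slice contour list; identical contours are
# rasterized once.
myo_from_contours <- function(contours, dim, pixel_spacing, slice_thickness) {
  if (!is.list(contours) || !length(contours)) {
    stopf("contours must be a non-empty per-slice list with $epi and $endo")
  }
  same <- length(contours) > 1L &&
    all(vapply(contours[-1L], function(ct) {
      identical(ct$epi, contours[[1L]]$epi) && identical(ct$endo, contours[[1L]]$endo)
    }, logical(1)))
  if (same) {
    m <- ring_mask_from_contours(contours[[1L]]$epi, contours[[1L]]$endo, dim)
    masks <- rep(list(m), length(contours))
  } else {
    masks <- lapply(contours, function(ct) {
      ring_mask_from_contours(ct$epi, ct$endo, dim)
    })
  }
  myo_mask(masks, pixel_spacing, slice_thickness)
}

# Angular sector index (0-based) of myocardial pixels about their centroid.
sector_of_pixels <- function(mask, n_sectors) {
  px <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(px)
  ang <- pixel_angles(px[, 1L], px[, 2L], ctr[1L], ctr[2L])
  list(pixels = px, sector = floor(ang / (360 / n_sectors)) %% n_sectors,
       angle = ang, center = ctr)
}

#' Automatic remote and high-SI ROI detection
#'
#' Emulates software detection of reference regions "based on the minimum and
#' maximum areas of signal intensity": the myocardial ring is divided into
#' `n_sectors` equal angular sectors about its centroid; every contiguous
#' (circularly wrapping) arc of `arc_width` sectors is scored by the mean SI
#' of its pixels. The remote ROI is the minimal-mean arc; the high-SI ROI is
#' the maximal-mean arc among arcs sharing no sector with the remote arc.
#' Ties are broken toward the lowest starting sector index, so the result is
#' deterministic, and the detection is invariant to adding a constant to all
#' SI values.
#'
#' @param lge_slice Signal-intensity matrix.
#' @param myo_slice Logical myocardial mask of the same dimension.
#' @param n_sectors Number of angular sectors (default 60).
#' @param arc_width Arc width in sectors (default 5).
#' @param slice_index Slice index recorded in the returned ROIs.
#' @return List with elements `remote` and `highsi`, both [roi_ref()].
#' @export
auto_detect_rois <- function(lge_slice, myo_slice, n_sectors = 60L,
                             arc_width = 5L, slice_index = 1L) {
  if (!any(myo_slice)) stopf("auto_detect_rois: empty myocardium")
  if (arc_width < 1L || n_sectors < arc_width) {
    stopf("auto_detect_rois: need n_sectors >= arc_width >= 1")
  }
  if (n_sectors < 2L * arc_width) {
    stopf("auto_detect_rois: n_sectors must be at least 2*arc_width for disjoint arcs")
  }
  sec <- sector_of_pixels(myo_slice, n_sectors)
  si <- lge_slice[pixels_to_index(as_pixels(sec$pixels), dim(lge_slice))]
  sums <- vapply(0:(n_sectors - 1L), function(s) sum(si[sec$sector == s]), numeric(1))
  cnts <- vapply(0:(n_sectors - 1L), function(s) sum(sec$sector == s), numeric(1))
  arc_sectors <- function(start) (start + 0:(arc_width - 1L)) %% n_sectors
  arc_mean <- vapply(0:(n_sectors - 1L), function(start) {
    s <- arc_sectors(start) + 1L
    n <- sum(cnts[s])
    if (n == 0) NA_real_ else sum(sums[s]) / n
  }, numeric(1))
  if (all(is.na(arc_mean))) stopf("auto_detect_rois: no pixels in any arc")
  remote_start <- which.min(arc_mean) - 1L      # first minimum: lowest index
  remote_secs <- arc_sectors(remote_start)
  cand <- order(-arc_mean, 0:(n_sectors - 1L), na.last = TRUE)
  high_start <- NA_integer_
  for (i in cand) {
    start <- i - 1L
    if (is.na(arc_mean[i])) next
    if (!any(arc_sectors(start) %in% remote_secs)) { high_start <- start; break }
  }
  if (is.na(high_start)) stopf("auto_detect_rois: no arc disjoint from the remote arc")
  pick <- function(start) {
    keep <- sec$sector %in% arc_sectors(start)
    sec$pixels[keep, , drop = FALSE]
  }
  list(
    remote = roi_ref(slice_index, pick(remote_start), "remote"),
    highsi = roi_ref(slice_index, pick(high_start), "high-SI")
  )
}

#' AHA 17-segment labels for a short-axis stack
#'
#' Slices (ordered base to apex) are partitioned into basal/mid/apical
#' thirds; basal and mid slices are divided into six 60-degree sectors and
#' apical slices into four 90-degree sectors, counted counter-clockwise (in
#' display orientation) from the anterior right-ventricular insertion.
#' Standard numbering applies: 1 basal anterior, 2 basal anteroseptal, ...,
#' 6 basal anterolateral; 7-12 the mid-cavity equivalents; 13 apical
#' anterior, 14 apical septal, 15 apical inferior, 16 apical lateral.
#' Counter-clockwise from the anterior insertion leads into the septum, so
#' the first sector after the insertion is the anteroseptal one. Segment 17
#' (apical cap) is assigned only when a cap slice is explicitly flagged,
#' since short-axis-only stacks rarely contain a true cap.
#'
#' @param myo A [myo_mask()].
#' @param rv_insertion_angle Angle of the anterior RV insertion in degrees
#'   (convention of [circle_polygon()] / `pixel_angles`: image-up = 90,
#'   counter-clockwise positive). Default 120 places the insertion
#'   anteroseptally for a septum-left short-axis display.
#' @param slice_thirds Optional explicit integer vector (1 = basal, 2 = mid,
#'   3 = apical) of length `n_slices`; required when fewer than 3 slices.
#' @param cap_slices Optional indices of apical-cap slices (labeled 17).
#' @return Object of class `segment_labels`: list of per-slice integer
#'   matrices (`NA` off-myocardium) plus the insertion angle.
#' @export
aha17_segments <- function(myo, rv_insertion_angle = 120, slice_thirds = NULL,
                           cap_slices = integer(0)) {
  n <- length(myo$masks)
  if (is.null(slice_thirds)) {
    if (n < 3L) stopf("aha17_segments: fewer than 3 slices; supply slice_thirds")
    slice_thirds <- as.integer(cut(seq_len(n), breaks = 3L, labels = FALSE))
  }
  if (length(slice_thirds) != n || !all(slice_thirds %in% 1:3)) {
    stopf("aha17_segments: slice_thirds must map every slice to 1 (basal), 2 (mid) or 3 (apical)")
  }
  basal_order <- c(2L, 3L, 4L, 5L, 6L, 1L)
  mid_order <- basal_order + 6L
  mid_order[6L] <- 7L
  apical_order <- c(14L, 15L, 16L, 13L)
  labels <- vector("list", n)
  for (s in seq_len(n)) {
    m <- myo$masks[[s]]
    lab <- matrix(NA_integer_, nrow(m), ncol(m))
    if (any(m)) {
      if (s %in% cap_slices) {
        lab[m] <- 17L
      } else {
        px <- which(m, arr.ind = TRUE)
        ctr <- colMeans(px)
        delta <- (pixel_angles(px[, 1L], px[, 2L], ctr[1L], ctr[2L]) -
                    rv_insertion_angle) %% 360
        seg <- if (slice_thirds[s] == 3L) {
          apical_order[floor(delta / 90) + 1L]
        } else if (slice_thirds[s] == 2L) {
          mid_order[floor(delta / 60) + 1L]
        } else {
          basal_order[floor(delta / 60) + 1L]
        }
        lab[pixels_to_index(as_pixels(px), dim(m))] <- seg
      }
    }
    labels[[s]] <- lab
  }
  structure(list(labels = labels, rv_insertion_angle = rv_insertion_angle,
                 slice_thirds = slice_thirds),
            class = "segment_labels")
}

#' Left-ventricular myocardial mass
#'
#' `mass = myocardial pixels x pixel area x slice thickness x density`,
#' reported in grams. Density defaults to the standard CMR convention of
#' 1.05 g/mL.
#'
#' @param myo A [myo_mask()].
#' @param density Myocardial density, g/mL.
#' @return Mass in grams.
#' @export
lv_mass <- function(myo, density = 1.05) {
  if (density <= 0) stopf("lv_mass: density must be positive")
  n_px <- sum(vapply(myo$masks, sum, numeric(1)))
  vol_ml <- n_px * myo$pixel_spacing^2 * myo$slice_thickness / 1000
  vol_ml * density
}
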