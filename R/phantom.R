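# Synthetic short-axis phantom: ring-shaped myocardium with patchy
# low-contrast lesions (non-ischemic mode) or a dense contiguous
# subendocardial wedge (ischemic mode), with a co-registered mid-LV ECV/T1
# map pair and ground-truth scar masks. Every downstream stage of the
# package is testable against these phantoms without any image download.

#' Phantom specification
#'
#' Defaults emulate the image structure of a non-ischemic short-axis LGE
#' study: an 8-slice stack with an annular myocardium, remote ECV 27.1%,
#' lesion ECV drawn between 31.5% and 40.6% (non-ischemic true-scar
#' patches) or 49.1-54.3% (ischemic), and lesion SI contrast of k multiples
#' of the nominal remote SD. Only the mid slice (index
#' `floor(n_slices/2) + 1`) carries T1/ECV data, mirroring single-slice
#' mid-LV T1 acquisition. Noise is additive Gaussian on SI (PSIR images are
#' signed, so no Rician floor is modeled); `noise_sd` defaults to
#' `remote_si_sd`, making remote pixels `Normal(remote_si_mean,
#' remote_si_sd^2)`. Setting `noise_sd = 0` gives exactly flat images:
#' remote SI equals `remote_si_mean` and every lesion pixel equals
#' `remote_si_mean + k * remote_si_sd`.
#'
#' @param n_slices Number of short-axis slices (base to apex).
#' @param image_size Square image size in pixels.
#' @param pixel_spacing In-plane spacing, mm.
#' @param slice_thickness Slice thickness, mm.
#' @param endo_radius,epi_radius Endocardial/epicardial radii, mm;
#'   `0 < endo < epi` and the epicardium must fit in the image.
#' @param mode `"non-ischemic"` (patchy mid-wall/epicardial blobs),
#'   `"ischemic"` (contiguous subendocardial wedge) or `"clean"` (no
#'   lesions).
#' @param n_patches Number of patches per lesioned slice (non-ischemic).
#' @param patch_contrast_k Lesion SI contrast in multiples of
#'   `remote_si_sd`, recycled per patch; `NULL` (default) draws each patch's
#'   k uniformly from 3-18, the plausible range for per-case thresholds.
#' @param target_scar_fraction Fraction of myocardial pixels that are scar
#'   on each lesioned slice, in `[0, 1]`.
#' @param remote_si_mean,remote_si_sd Remote SI mean and nominal SD
#'   (arbitrary units); `remote_si_sd > 0`.
#' @param remote_ecv_pct Remote-myocardium ECV, percent (default 27.1).
#' @param scar_ecv_pct Lesion ECV, percent, recycled per patch; `NULL`
#'   (default) draws uniformly from `[31.5, 40.6]` (non-ischemic true-scar
#'   patches) or `[49.1, 54.3]` (ischemic).
#' @param hematocrit Hematocrit fraction in (0, 1).
#' @param noise_sd Additive Gaussian SI noise SD; `NULL` defaults to
#'   `remote_si_sd`.
#' @param lesion_slices Indices of slices carrying lesions (default: all).
#' @param wedge_angle_deg Angular extent of the ischemic wedge, degrees.
#' @param t1_myo_pre_ms,t1_blood_pre_ms,t1_blood_post_ms Constants used to
#'   synthesize the mid-slice T1 pair (native myocardial T1, blood pre/post
#'   T1, ms). Post-contrast myocardial T1 is solved per pixel from the ECV
#'   formula, so computing ECV from the synthesized pair reproduces the
#'   specified ECV map by construction.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 8L, image_size = 96L, pixel_spacing = 1.0,
                         slice_thickness = 8.0, endo_radius = 16,
                         epi_radius = 26,
                         mode = c("non-ischemic", "ischemic", "clean"),
                         n_patches = 3L, patch_contrast_k = NULL,
                         target_scar_fraction = 0.05,
                         remote_si_mean = 100, remote_si_sd = 10,
                         remote_ecv_pct = 27.1, scar_ecv_pct = NULL,
                         hematocrit = 0.42, noise_sd = NULL,
                         lesion_slices = NULL, wedge_angle_deg = 90,
                         t1_myo_pre_ms = 1200, t1_blood_pre_ms = 1900,
                         t1_blood_post_ms = 380, seed = 1L) {
  mode <- match.arg(mode)
  noise_sd <- noise_sd %||% remote_si_sd
  spec <- list(n_slices = as.integer(n_slices), image_size = as.integer(image_size),
               pixel_spacing = pixel_spacing, slice_thickness = slice_thickness,
               endo_radius = endo_radius, epi_radius = epi_radius, mode = mode,
               n_patches = as.integer(n_patches),
               patch_contrast_k = patch_contrast_k,
               target_scar_fraction = target_scar_fraction,
               remote_si_mean = remote_si_mean, remote_si_sd = remote_si_sd,
               remote_ecv_pct = remote_ecv_pct, scar_ecv_pct = scar_ecv_pct,
               hematocrit = hematocrit, noise_sd = noise_sd,
               lesion_slices = lesion_slices,
               wedge_angle_deg = wedge_angle_deg,
               t1_myo_pre_ms = t1_myo_pre_ms,
               t1_blood_pre_ms = t1_blood_pre_ms,
               t1_blood_post_ms = t1_blood_post_ms, seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  if (spec$n_slices < 1L) stopf("phantom_spec: n_slices must be >= 1")
  if (spec$endo_radius <= 0 || spec$endo_radius >= spec$epi_radius) {
    stopf("phantom_spec: need 0 < endo_radius < epi_radius")
  }
  r_epi_px <- spec$epi_radius / spec$pixel_spacing
  if (r_epi_px + 2 > spec$image_size / 2) {
    stopf("phantom_spec: epicardium (%.1f px radius) does not fit in a %d px image",
          r_epi_px, spec$image_size)
  }
  if (spec$target_scar_fraction < 0 || spec$target_scar_fraction > 1) {
    stopf("phantom_spec: target_scar_fraction must be in [0, 1]")
  }
  if (spec$remote_si_sd <= 0) stopf("phantom_spec: remote_si_sd must be > 0")
  if (spec$hematocrit <= 0 || spec$hematocrit >= 1) {
    stopf("phantom_spec: hematocrit must lie strictly between 0 and 1")
  }
  if (spec$noise_sd < 0) stopf("phantom_spec: noise_sd must be >= 0")
  if (spec$n_patches < 1L) stopf("phantom_spec: n_patches must be >= 1")
  if (!is.null(spec$lesion_slices) &&
      (!all(spec$lesion_slices %in% seq_len(spec$n_slices)))) {
    stopf("phantom_spec: lesion_slices outside 1..%d", spec$n_slices)
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s, %d slices of %d px, ring %.0f-%.0f mm, target scar %.1f%%, seed %d\n",
              x$mode, x$n_slices, x$image_size, x$endo_radius, x$epi_radius,
              100 * x$target_scar_fraction, x$seed))
  invisible(x)
}

# Lesion placement on one slice. Non-ischemic: Gaussian-bump fields centered
# in the mid-wall/epicardial half of the ring, thresholded to the target
# pixel count (patchy blobs). Ischemic: pixels of a random angular wedge
# taken subendocardium-first (a contiguous transmural-growing wedge).
# Returns linear pixel indices and the owning patch id for each.
place_lesions <- function(spec, ring, radius_px, ang, rows, cols,
                          r_endo_px, r_epi_px, ctr) {
  n_ring <- sum(ring)
  m <- round(spec$target_scar_fraction * n_ring)
  if (m == 0L) return(list(pix = integer(0), patch = integer(0), n_patches = 0L))
  if (spec$mode == "ischemic") {
    theta0 <- stats::runif(1, 0, 360)
    rel <- (ang - theta0) %% 360
    elig <- which(ring & rel <= spec$wedge_angle_deg)
    if (length(elig) < m) {
      stopf("generate_phantom: target_scar_fraction %.3f unreachable within a %.0f-degree wedge (%d eligible px, need %d)",
            spec$target_scar_fraction, spec$wedge_angle_deg, length(elig), m)
    }
    ord <- order(radius_px[elig], rel[elig])
    list(pix = elig[ord[seq_len(m)]], patch = rep(1L, m), n_patches = 1L)
  } else {
    half <- (r_endo_px + r_epi_px) / 2
    elig <- which(ring & radius_px >= half)
    if (length(elig) < m) {
      stopf("generate_phantom: target_scar_fraction %.3f unreachable in the mid-wall/epicardial half (%d eligible px, need %d)",
            spec$target_scar_fraction, length(elig), m)
    }
    np <- spec$n_patches
    th <- stats::runif(np, 0, 2 * pi)
    rr <- stats::runif(np, min(half + 0.5, r_epi_px - 0.5), r_epi_px - 0.5)
    width <- pmax(1.2, sqrt(m / np / pi)) * stats::runif(np, 0.8, 1.2)
    crow <- ctr - rr * sin(th)
    ccol <- ctr + rr * cos(th)
    er <- rows[elig]
    ec <- cols[elig]
    field <- matrix(0, length(elig), np)
    for (p in seq_len(np)) {
      d2 <- (er - crow[p])^2 + (ec - ccol[p])^2
      field[, p] <- exp(-d2 / (2 * width[p]^2))
    }
    best <- apply(field, 1L, max)
    owner <- max.col(field, ties.method = "first")
    ord <- order(-best, elig)          # deterministic tie-break
    pick <- ord[seq_len(m)]
    list(pix = elig[pick], patch = owner[pick], n_patches = np)
  }
}

#' Generate a synthetic short-axis phantom
#'
#' Builds the LGE stack, per-slice contours, mid-slice T1 pair (from which
#' [compute_ecv()] reproduces the specified ECV map to machine precision),
#' ground-truth scar masks and the true scar percent. The myocardium is
#' rasterized from the emitted circular contours, so truth masks are exact
#' subsets of the contour-derived myocardium used downstream.
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom_output` with elements `lge`
#'   ([lge_stack()]), `contours`, `t1pair` ([t1_pair()]), `ecv_specified`
#'   (the constructed mid-slice [ecv_map()]), `truth_masks`,
#'   `truth_scar_percent`, and `spec_echo`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(mode = "clean", target_scar_fraction = 0,
#'                                     image_size = 48, epi_radius = 14,
#'                                     endo_radius = 8, n_slices = 3))
#' ph$truth_scar_percent  # 0
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("generate_phantom: spec must be a phantom_spec")
  validate_phantom_spec(spec)
  sz <- spec$image_size
  ctr <- (sz + 1) / 2
  r_endo_px <- spec$endo_radius / spec$pixel_spacing
  r_epi_px <- spec$epi_radius / spec$pixel_spacing
  epi_poly <- circle_polygon(ctr, ctr, r_epi_px)
  endo_poly <- circle_polygon(ctr, ctr, r_endo_px)
  ring <- ring_mask_from_contours(epi_poly, endo_poly, dim = c(sz, sz))
  rows <- row(ring)
  cols <- col(ring)
  radius_px <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  ang <- pixel_angles(rows, cols, ctr, ctr)
  mid <- floor(spec$n_slices / 2) + 1L
  lesioned <- if (spec$mode == "clean") integer(0) else {
    spec$lesion_slices %||% seq_len(spec$n_slices)
  }

  si <- array(spec$remote_si_mean, dim = c(sz, sz, spec$n_slices))
  truth <- array(FALSE, dim = c(sz, sz, spec$n_slices))
  mid_pix <- integer(0)
  mid_owner <- integer(0)
  mid_ecv_per_patch <- numeric(0)

  with_seed(spec$seed, {
    for (s in seq_len(spec$n_slices)) {
      if (!(s %in% lesioned) || spec$target_scar_fraction <= 0) next
      les <- place_lesions(spec, ring, radius_px, ang, rows, cols,
                           r_endo_px, r_epi_px, ctr)
      if (!length(les$pix)) next
      np <- les$n_patches
      k <- spec$patch_contrast_k %||% stats::runif(np, 3, 18)
      k <- rep_len(k, np)
      ecv_default <- if (spec$mode == "ischemic") {
        stats::runif(np, 49.1, 54.3)
      } else {
        stats::runif(np, 31.5, 40.6)   # [34 - 6.6, 34 + 6.6] truncated at the cutoff
      }
      patch_ecv <- rep_len(spec$scar_ecv_pct %||% ecv_default, np)
      sl <- si[, , s]
      sl[les$pix] <- spec$remote_si_mean + k[les$patch] * spec$remote_si_sd
      si[, , s] <- sl
      tr <- truth[, , s]
      tr[les$pix] <- TRUE
      truth[, , s] <- tr
      if (s == mid) {
        mid_pix <- les$pix
        mid_owner <- les$patch
        mid_ecv_per_patch <- patch_ecv
      }
    }
    if (spec$noise_sd > 0) {
      si <- si + array(stats::rnorm(length(si), 0, spec$noise_sd), dim = dim(si))
    }
  })

  # Mid-slice ECV map and T1 pair (exactly invertible by construction).
  ecv_mid <- matrix(NA_real_, sz, sz)
  ecv_mid[ring] <- spec$remote_ecv_pct
  if (length(mid_pix)) ecv_mid[mid_pix] <- mid_ecv_per_patch[mid_owner]
  d_r1_blood <- 1 / spec$t1_blood_post_ms - 1 / spec$t1_blood_pre_ms
  t1_pre <- matrix(NA_real_, sz, sz)
  t1_pre[ring] <- spec$t1_myo_pre_ms
  r1_post <- 1 / t1_pre + (ecv_mid / 100) * d_r1_blood / (1 - spec$hematocrit)
  t1_post <- 1 / r1_post
  pair <- t1_pair(t1_pre, t1_post, spec$t1_blood_pre_ms, spec$t1_blood_post_ms,
                  spec$hematocrit)

  contours <- rep(list(list(epi = epi_poly, endo = endo_poly)), spec$n_slices)
  truth_masks <- lapply(seq_len(spec$n_slices), function(s) truth[, , s])
  myo <- myo_mask(rep(list(ring), spec$n_slices), spec$pixel_spacing,
                  spec$slice_thickness)
  truth_res <- scar_result(truth_masks, myo, density = 1.05)

  structure(list(
    lge = lge_stack(si, spec$pixel_spacing, spec$slice_thickness, mid),
    contours = contours,
    t1pair = pair,
    ecv_specified = ecv_map(ecv_mid, ring),
    truth_masks = truth_masks,
    truth_scar_percent = truth_res$scar_percent,
    spec_echo = spec
  ), class = "phantom_output")
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("<phantom_output> %s phantom, %d slices, truth scar %.2f%% (seed %d)\n",
              x$spec_echo$mode, x$spec_echo$n_slices, x$truth_scar_percent,
              x$spec_echo$seed))
  invisible(x)
}
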