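make_roi <- function(px, label = "remote") roi_ref(1L, px, label)

test_that("remote statistics use the sample SD", {
  si <- matrix(0, 5, 5)
  si[1, 1] <- 90; si[2, 1] <- 100; si[3, 1] <- 110
  st <- remote_stats(si, make_roi(cbind(1:3, 1)))
  expect_equal(st$mean_si, 100)
  expect_equal(st$sd_si, 10)           # sd with n-1 denominator
  expect_equal(st$n_pixels, 3L)
  stc <- remote_stats(matrix(7, 4, 4), make_roi(cbind(1:4, 2)))
  expect_equal(stc$sd_si, 0)
  expect_error(remote_stats(si, make_roi(cbind(1, 1))), "2 ROI pixels")
})

test_that("n-SD mask uses a strict inequality above mean + n*SD", {
  st <- nominal_remote_stats(100, 10)
  si <- matrix(0, 2, 2)
  si[1, 1] <- 151; si[1, 2] <- 150; si[2, 1] <- 149
  myo <- matrix(TRUE, 2, 2)
  out <- nsd_mask(si, myo, st, 5)
  expect_identical(out$mask, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_equal(out$selection$absolute_threshold, 150)
  # n = 0: pixels above the remote mean
  out0 <- nsd_mask(si, myo, st, 0)
  expect_equal(sum(out0$mask), 3)
  expect_error(nsd_mask(si, myo, nominal_remote_stats(100, 0), 5), "degenerate")
  expect_error(nsd_mask(si, myo, st, -1), "non-negative")
})

test_that("FWHM thresholds follow the half-maximum formulas", {
  si <- matrix(100, 6, 6)
  si[3, 3] <- 400; si[3, 4] <- 260; si[4, 3] <- 199
  myo <- matrix(TRUE, 6, 6)
  seed <- make_roi(cbind(3, 3), "high-SI")
  plain <- fwhm_mask(si, myo, seed)
  expect_equal(plain$selection$absolute_threshold, 200)        # S_max / 2
  expect_identical(sum(plain$mask), 2L)                        # 400 and 260; 199 < 200
  corr <- fwhm_mask(si, myo, seed, baseline_corrected = TRUE,
                    remote = nominal_remote_stats(100, 10))
  expect_equal(corr$selection$absolute_threshold, 250)         # 100 + 0.5*(400-100)
  # ">=" inclusion at the threshold
  si2 <- si; si2[5, 5] <- 200
  expect_true(fwhm_mask(si2, myo, seed)$mask[5, 5])
  expect_error(fwhm_mask(si, myo, seed, baseline_corrected = TRUE,
                         remote = nominal_remote_stats(500, 10)),
               "does not exceed")
})

test_that("n-SD and FWHM masks agree when thresholds coincide", {
  set.seed(5)
  si <- matrix(rnorm(400, 100, 10), 20, 20)
  si[5, 5] <- 300
  myo <- matrix(TRUE, 20, 20)
  st <- nominal_remote_stats(100, 10)
  # FWHM corrected threshold = 100 + 0.5*200 = 200 = mean + 10*SD
  fw <- fwhm_mask(si, myo, make_roi(cbind(5, 5), "high-SI"),
                  baseline_corrected = TRUE, remote = st)
  ns <- nsd_mask(si, myo, st, 10)
  expect_equal(fw$selection$absolute_threshold, ns$selection$absolute_threshold)
  # masks can differ only at pixels exactly on the threshold
  boundary <- si == 200
  expect_identical(fw$mask & !boundary, ns$mask & !boundary)
})

test_that("threshold propagation re-estimates remote statistics per slice", {
  ph <- generate_phantom(small_spec(n_patches = 1L, patch_contrast_k = 8,
                                    target_scar_fraction = 0.05, seed = 12))
  stack <- ph$lge
  dims <- dim(stack$data)
  ring <- ring_mask_from_contours(ph$contours[[1]]$epi, ph$contours[[1]]$endo,
                                  dims[1:2])
  myo <- myo_mask(rep(list(ring), dims[3]), 1, 8)
  mid <- stack$mid_slice
  rois <- auto_detect_rois(stack$data[, , mid], ring, slice_index = mid)
  st <- remote_stats(stack$data[, , mid], rois$remote)
  sel <- nsd_mask(stack$data[, , mid], ring, st, 5)$selection

  masks <- propagate_threshold(stack, myo, sel, per_slice_remote = TRUE)
  expect_length(masks, dims[3])
  expect_identical(masks[[mid]], nsd_mask(stack$data[, , mid], ring, st, 5)$mask)

  # per-slice rescaling: scaling one slice's SI by 2 leaves its mask
  # unchanged under per-slice remote re-estimation, but not under the
  # absolute mid-slice threshold
  scaled <- stack
  scaled$data[, , 2] <- scaled$data[, , 2] * 2
  m_rel <- propagate_threshold(scaled, myo, sel, per_slice_remote = TRUE)
  expect_identical(m_rel[[2]], masks[[2]])
  m_abs <- propagate_threshold(scaled, myo, sel, per_slice_remote = FALSE)
  expect_false(identical(m_abs[[2]], masks[[2]]))

  # a stack of identical slices yields identical masks
  flat <- lge_stack(array(rep(stack$data[, , mid], 3), c(dims[1:2], 3)), 1, 8)
  myo3 <- myo_mask(rep(list(ring), 3), 1, 8)
  m3 <- propagate_threshold(flat, myo3, sel)
  expect_identical(m3[[1]], m3[[2]])
  expect_identical(m3[[2]], m3[[3]])

  # single-slice stack reduces to the mid-slice mask
  one <- lge_stack(array(stack$data[, , mid], c(dims[1:2], 1)), 1, 8)
  m1 <- propagate_threshold(one, myo_mask(list(ring), 1, 8), sel)
  expect_identical(m1[[1]], masks[[mid]])
})

test_that("component filtering matches a union-find oracle and is idempotent", {
  # hand case: components of size 3 (removed at min 5)
  m <- matrix(FALSE, 10, 10)
  m[2, 2:4] <- TRUE
  expect_false(any(filter_components(m, 5L)))
  expect_identical(filter_components(m, 0L), m)

  # sizes 4 and 20 with 8-connectivity: only the 20-px component survives
  m2 <- matrix(FALSE, 12, 12)
  m2[1:2, 1:2] <- TRUE                       # 4 px
  m2[6:9, 5:9] <- TRUE                       # 20 px
  f2 <- filter_components(m2, 5L, connectivity = 8L)
  expect_equal(sum(f2), 20)
  expect_true(all(f2[6:9, 5:9]))

  # random masks, both connectivities, against the union-find oracle
  set.seed(99)
  for (conn in c(4L, 8L)) {
    for (i in 1:5) {
      rm <- matrix(runif(15 * 15) < 0.35, 15, 15)
      lab_pkg <- ecvlge:::label_components(rm, conn)
      lab_ora <- oracle_components(rm, conn)
      # same partition: component ids agree up to relabeling
      expect_equal(max(lab_pkg), max(lab_ora))
      expect_true(all(tapply(lab_ora[rm], lab_pkg[rm],
                             function(v) length(unique(v))) == 1))
      for (minpx in c(0L, 3L, 6L)) {
        once <- filter_components(rm, minpx, conn)
        expect_identical(filter_components(once, minpx, conn), once)
      }
    }
  }
})

test_that("diagonal pixels merge under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- m[2, 2] <- TRUE
  expect_equal(max(ecvlge:::label_components(m, 8L)), 1L)
  expect_equal(max(ecvlge:::label_components(m, 4L)), 2L)
})

test_that("scar result arithmetic and segmental bookkeeping are exact", {
  myo_m <- matrix(FALSE, 20, 20)
  myo_m[1:10, 1:10] <- TRUE                  # 100 px
  scar_m <- matrix(FALSE, 20, 20)
  scar_m[1:5, 1:2] <- TRUE                   # 10 px
  myo <- myo_mask(list(myo_m), pixel_spacing = 1, slice_thickness = 10)
  res <- scar_result(list(scar_m), myo)
  expect_equal(res$scar_mass_g, 0.105)
  expect_equal(res$lv_mass_g, 1.05)
  expect_equal(res$scar_percent, 10)
  expect_equal(res$scar_percent, 100 * res$scar_mass_g / res$lv_mass_g)

  empty <- scar_result(list(scar_m & FALSE), myo)
  expect_equal(empty$scar_mass_g, 0)
  expect_equal(empty$scar_percent, 0)

  expect_error(scar_result(list(matrix(TRUE, 20, 20)), myo), "outside the myocardium")
})

test_that("scar confined to one segment reports only that segment", {
  fx <- ring_fixture()
  myo <- myo_mask(rep(list(fx$mask), 3), 1, 8)
  seg <- aha17_segments(myo, rv_insertion_angle = 120)
  # take all pixels of one mid-slice segment as scar
  lab <- seg$labels[[2]]
  target <- sort(unique(lab[!is.na(lab)]))[1]
  scar_m <- !is.na(lab) & lab == target
  masks <- list(fx$mask & FALSE, scar_m, fx$mask & FALSE)
  res <- scar_result(masks, myo, seg)
  ps <- res$per_segment_percent
  # the mid-cavity segment exists only on the mid slice, so it is fully scarred
  expect_equal(unname(ps[as.character(target)]), 100)
  expect_true(all(ps[setdiff(names(ps), as.character(target))] == 0))
  expect_equal(res$scar_percent, 100 * sum(scar_m) / (3 * sum(fx$mask)))
})

test_that("scar pixel count is non-increasing in n", {
  ph <- generate_phantom(small_spec(seed = 44))
  mid <- ph$lge$mid_slice
  ring <- ring_mask_from_contours(ph$contours[[1]]$epi, ph$contours[[1]]$endo,
                                  dim(ph$lge$data)[1:2])
  rois <- auto_detect_rois(ph$lge$data[, , mid], ring, slice_index = mid)
  st <- remote_stats(ph$lge$data[, , mid], rois$remote)
  counts <- vapply(seq(0, 20, by = 0.5), function(n) {
    sum(nsd_mask(ph$lge$data[, , mid], ring, st, n)$mask)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
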