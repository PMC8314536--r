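test_that("ECV criteria classify the high-SI ROI with an inclusive cutoff", {
  cfg <- ecv_guided_config()
  expect_equal(classify_roi(69.3, cfg), "scar")
  expect_equal(classify_roi(26.5, cfg), "non-scar")
  expect_equal(classify_roi(31.5, cfg), "scar")        # boundary inclusive
  expect_equal(classify_roi(31.49999, cfg), "non-scar")
  # native-T1 alternative criterion
  expect_equal(classify_roi(1339, cfg, criterion = "nt1"), "scar")
  expect_equal(classify_roi(1200, cfg, criterion = "nt1"), "non-scar")
  expect_error(classify_roi(NA_real_, cfg), "finite")
})

test_that("config validation enforces its invariants", {
  expect_error(ecv_guided_config(ecv_cutoff = 0), "cutoff")
  expect_error(ecv_guided_config(n_grid = c(2, 1)), "increasing")
  expect_error(ecv_guided_config(nonscar_tolerance_px = -1), ">= 0")
})

test_that("scar-scenario selection maximizes Dice with ties toward larger n", {
  # flat patch at mean + 10.2 SD; ECV mask identical to the patch.
  # The n-SD mask equals the patch for every n < 10.2, so the largest such
  # grid value (10 on an integer-friendly grid) must win with Dice 1.
  si <- matrix(100, 30, 30)
  myo <- matrix(FALSE, 30, 30)
  myo[5:25, 5:25] <- TRUE
  patch <- matrix(FALSE, 30, 30)
  patch[10:14, 10:14] <- TRUE
  si[patch] <- 100 + 10.2 * 10
  st <- nominal_remote_stats(100, 10)
  cfg <- ecv_guided_config(n_grid = seq(1, 20, by = 0.5))
  sel <- select_n_scar(si, myo, st, patch, cfg)
  expect_equal(sel$n, 10)
  expect_equal(sel$dice, 1)
  expect_false(sel$degenerate)
  # analytic oracle: largest grid value strictly below the minimal z-score
  z_min <- (min(si[patch]) - 100) / 10
  expect_equal(sel$n, max(cfg$n_grid[cfg$n_grid < z_min]))
})

test_that("scar-scenario selection degenerates gracefully when nothing is highlighted", {
  si <- matrix(100, 10, 10)
  myo <- matrix(TRUE, 10, 10)
  patch <- matrix(FALSE, 10, 10); patch[2, 2] <- TRUE
  st <- nominal_remote_stats(200, 10)      # everything far below the remote mean
  cfg <- ecv_guided_config(n_grid = 1:5)
  expect_warning(sel <- select_n_scar(si, myo, st, patch, cfg), "smallest n")
  expect_equal(sel$n, 1)
  expect_true(sel$degenerate)
  expect_error(select_n_scar(si, myo, st, patch & FALSE, cfg), "empty")
})

test_that("non-scar selection picks the closest non-highlighting threshold", {
  si <- matrix(100, 20, 20)
  myo <- matrix(TRUE, 20, 20)
  roi_px <- cbind(5:9, 5)
  si[5, 5] <- 100 + 12.4 * 10              # ROI max at mean + 12.4 SD
  st <- nominal_remote_stats(100, 10)
  cfg <- ecv_guided_config(n_grid = 1:20)
  roi <- roi_ref(1L, roi_px, "high-SI")
  sel <- select_n_nonscar(si, myo, st, roi, cfg)
  expect_equal(sel$n, 13)                  # smallest integer n with 13 SD > 12.4 SD
  # ROI entirely below mean + 1 SD -> grid minimum
  si2 <- matrix(100, 20, 20); si2[roi_px] <- 105
  expect_equal(select_n_nonscar(si2, myo, st, roi, cfg)$n, 1)
  # no threshold suppresses the ROI -> largest n with warning
  si3 <- matrix(100, 20, 20); si3[5, 5] <- 100 + 50 * 10
  expect_warning(s3 <- select_n_nonscar(si3, myo, st, roi, cfg), "largest n")
  expect_equal(s3$n, 20)
  expect_true(s3$degenerate)
})

test_that("the non-scar tolerance changes the selected threshold", {
  si <- matrix(100, 20, 20)
  myo <- matrix(TRUE, 20, 20)
  roi_px <- cbind(2:11, 3)
  si[2:4, 3] <- 100 + 5.4 * 10             # 3-pixel spillover above 5 SD
  si[5:11, 3] <- 105
  st <- nominal_remote_stats(100, 10)
  cfg0 <- ecv_guided_config(n_grid = 1:20, nonscar_tolerance_px = 0)
  cfg3 <- ecv_guided_config(n_grid = 1:20, nonscar_tolerance_px = 3)
  roi <- roi_ref(1L, roi_px, "high-SI")
  n0 <- select_n_nonscar(si, myo, st, roi, cfg0)$n
  n3 <- select_n_nonscar(si, myo, st, roi, cfg3)$n
  expect_equal(n0, 6)
  expect_equal(n3, 1)
  expect_gt(n0, n3)
})

test_that("clean phantom yields the non-scar scenario with zero scar", {
  ph <- generate_phantom(small_spec(mode = "clean", target_scar_fraction = 0,
                                    seed = 6))
  rep <- suppressWarnings(
    run_ecv_guided(ph$lge, ph$contours, compute_ecv(ph$t1pair)))
  expect_equal(rep$scenario, "non-scar")
  expect_equal(rep$scar$scar_percent, 0)
  expect_true(is.na(rep$mid_slice_dice))
  expect_true(rep$selected_n %in% rep$config$n_grid)
})

test_that("ECV-guided analysis recovers the phantom's true scar burden", {
  spec <- phantom_spec(mode = "non-ischemic", n_patches = 2L,
                       patch_contrast_k = 8, target_scar_fraction = 0.05,
                       scar_ecv_pct = 58.3, seed = 42)
  ph <- generate_phantom(spec)
  rep <- suppressWarnings(
    run_ecv_guided(ph$lge, ph$contours, compute_ecv(ph$t1pair)))
  expect_equal(rep$scenario, "scar")
  expect_lt(abs(rep$scar$scar_percent - ph$truth_scar_percent), 1)
  expect_gte(rep$mid_slice_dice, 0.8)
  expect_true(rep$selected_n %in% rep$config$n_grid)
})

test_that("a sub-cutoff mid slice can still show scar elsewhere after propagation", {
  # lesions everywhere except the mid slice: the high-SI ROI on the mid
  # slice has remote-level ECV (non-scar scenario), but supra-threshold
  # lesions on other slices survive propagation
  spec <- small_spec(n_patches = 2L, patch_contrast_k = 12,
                     target_scar_fraction = 0.06,
                     lesion_slices = c(1L, 2L, 4L), seed = 15)
  ph <- generate_phantom(spec)
  expect_equal(sum(ph$truth_masks[[ph$lge$mid_slice]]), 0)
  rep <- suppressWarnings(
    run_ecv_guided(ph$lge, ph$contours, compute_ecv(ph$t1pair)))
  expect_equal(rep$scenario, "non-scar")
  expect_lt(rep$roi_ecv, 31.5)
  expect_gt(rep$scar$scar_percent, 0)
  # scenario consistency: no scar on the mid slice itself
  expect_equal(rep$scar$per_slice_px[ph$lge$mid_slice], 0)
})

test_that("refining the n grid never decreases the achieved Dice", {
  ph <- generate_phantom(small_spec(scar_ecv_pct = 58.3, patch_contrast_k = 6,
                                    seed = 77))
  coarse <- ecv_guided_config(n_grid = seq(1, 20, by = 1))
  fine <- ecv_guided_config(n_grid = seq(1, 20, by = 0.5))
  r1 <- suppressWarnings(run_ecv_guided(ph$lge, ph$contours,
                                        compute_ecv(ph$t1pair), coarse))
  r2 <- suppressWarnings(run_ecv_guided(ph$lge, ph$contours,
                                        compute_ecv(ph$t1pair), fine))
  expect_equal(r1$scenario, "scar")
  expect_gte(r2$mid_slice_dice, r1$mid_slice_dice)
})

test_that("identical inputs give identical reports", {
  ph <- generate_phantom(small_spec(seed = 50, scar_ecv_pct = 58.3))
  e <- compute_ecv(ph$t1pair)
  a <- suppressWarnings(run_ecv_guided(ph$lge, ph$contours, e))
  b <- suppressWarnings(run_ecv_guided(ph$lge, ph$contours, e))
  expect_identical(a$selected_n, b$selected_n)
  expect_identical(a$scar$scar_percent, b$scar$scar_percent)
  expect_identical(a$scar$per_segment_percent, b$scar$per_segment_percent)
})

test_that("a missing mid-slice ECV map is a hard error", {
  ph <- generate_phantom(small_spec(seed = 9))
  empty <- ecv_map(matrix(NA_real_, 64, 64))
  expect_error(run_ecv_guided(ph$lge, ph$contours, empty), "no valid ECV")
  expect_error(run_ecv_guided(ph$lge, ph$contours[1:2], compute_ecv(ph$t1pair)),
               "all 4 slices")
})
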