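test_that("envelope of a constant-amplitude sinusoid is flat near 0 dB", {
  t <- seq(0, 2e-6, by = 1e-8)
  rf <- matrix(sin(2 * pi * 5e6 * t), nrow = 1)
  b <- toy_bscan(rf)
  env <- compute_envelope(b)
  core <- env$db[1, 20:(length(t) - 20)] # away from transform edge effects
  expect_true(all(core > -0.5))
  expect_equal(max(env$db), 0)
})

test_that("a 10x amplitude difference between lines reads as 20 dB", {
  t <- seq(0, 2e-6, by = 1e-8)
  rf <- rbind(sin(2 * pi * 5e6 * t), 10 * sin(2 * pi * 5e6 * t))
  env <- compute_envelope(toy_bscan(rf))
  peak1 <- max(env$db[1, ])
  peak2 <- max(env$db[2, ])
  expect_equal(peak2 - peak1, 20, tolerance = 1e-6)
})

test_that("all-zero scans are rejected by envelope computation", {
  expect_error(compute_envelope(toy_bscan(matrix(0, 2, 100))), "brightest")
})

test_that("threshold is inclusive and applied relative to the scan-wide peak", {
  env <- structure(
    list(db = matrix(c(0, -20, -26, -30), nrow = 1), sampling_rate = 1e8,
         line_pitch = 0.5, sound_speed_assumed = 1540, depth_origin = 0),
    class = "envelope_image"
  )
  expect_identical(as.vector(threshold_mask(env, -26)),
                   c(TRUE, TRUE, TRUE, FALSE))
  env$db[] <- 0
  expect_true(all(threshold_mask(env, -26)))
  expect_error(threshold_mask(env, 3))
})

test_that("closing matches a brute-force morphology oracle on small grids", {
  kern <- qusim:::ellipse_kernel(2, 2)
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(stats::runif(100) < 0.4, 10, 10)
    expect_identical(clean_mask(m, c(2, 2)), brute_close(m, kern))
  }
  # a one-pixel hole inside a solid block is filled
  m <- matrix(FALSE, 10, 10)
  m[3:8, 3:8] <- TRUE
  m[5, 5] <- FALSE
  expect_true(clean_mask(m, c(1, 1))[5, 5])
})

test_that("closing with radius 0 is the identity and preserves empty masks", {
  m <- matrix(stats::runif(50) < 0.5, 5, 10)
  expect_identical(clean_mask(m, 0), m)
  empty <- matrix(FALSE, 5, 10)
  expect_identical(clean_mask(empty, c(3, 2)), empty)
})

test_that("largest-region selection agrees with a flood-fill labelling oracle", {
  scan <- toy_bscan(matrix(0.1, 10, 12))
  # two components: 3x4 = 12 px and 2x3 = 6 px
  m <- matrix(FALSE, 10, 12)
  m[1:3, 1:4] <- TRUE
  m[7:8, 9:11] <- TRUE
  roi <- select_largest_region(m, scan)
  expect_equal(roi$region_count_before_selection, 2)
  expect_equal(sum(roi$mask), 12)
  expect_true(all(roi$mask[1:3, 1:4]))

  set.seed(12)
  for (i in 1:8) {
    for (conn in c(4, 8)) {
      m <- matrix(stats::runif(10 * 12) < 0.35, 10, 12)
      if (!any(m)) next
      lab <- brute_label(m, conn)
      sizes <- tabulate(lab[lab > 0])
      roi <- select_largest_region(m, scan, connectivity = conn)
      expect_equal(roi$region_count_before_selection, max(lab))
      expect_equal(sum(roi$mask), max(sizes))
    }
  }
  expect_error(select_largest_region(matrix(FALSE, 3, 3), scan), "Empty")
})

test_that("diagonal-only pixels are one region at 8- but not 4-connectivity", {
  scan <- toy_bscan(matrix(0.1, 5, 5))
  m <- matrix(FALSE, 5, 5)
  m[cbind(1:4, 1:4)] <- TRUE
  expect_equal(select_largest_region(m, scan, 8)$region_count_before_selection, 1)
  expect_equal(select_largest_region(m, scan, 4)$region_count_before_selection, 4)
})

test_that("mask application zeroes outside, preserves inside, and is idempotent", {
  set.seed(3)
  rf <- matrix(stats::rnorm(200), 10, 20)
  scan <- toy_bscan(rf)
  m <- matrix(FALSE, 10, 20)
  m[4:7, 5:15] <- TRUE
  seg <- apply_mask(scan, m)
  expect_identical(seg$rf_masked[m], rf[m])
  expect_true(all(seg$rf_masked[!m] == 0))
  seg2 <- apply_mask(seg$source, seg$mask)
  expect_identical(seg2$rf_masked, seg$rf_masked)

  all_true <- matrix(TRUE, 10, 20)
  expect_identical(apply_mask(scan, all_true)$rf_masked, rf)
  one <- matrix(FALSE, 10, 20); one[2, 3] <- TRUE
  expect_equal(sum(apply_mask(scan, one)$rf_masked != 0), 1)
  expect_error(apply_mask(scan, matrix(TRUE, 3, 3)), "shape")
})

test_that("ROI depth bookkeeping follows the assumed-sound-speed conversion", {
  scan <- toy_bscan(matrix(0.1, 4, 100), sampling_rate = 100e6,
                    sound_speed = 1540)
  m <- matrix(FALSE, 4, 100)
  m[, 11:40] <- TRUE
  roi <- select_largest_region(m, scan)
  step_mm <- 1540 / (2 * 100e6) * 1e3
  expect_equal(roi$d1, 10 * step_mm)
  expect_equal(roi$d2, 39 * step_mm)
  expect_equal(roi$per_line_depths$top_mm, rep(10 * step_mm, 4))
})

test_that("segmentation recovers the tissue band of a generated phantom", {
  ss <- speckle_scan_set()
  seg <- segment_roi(ss$sample_scan)
  expect_equal(seg$mask$region_count_before_selection >= 1, TRUE)
  iou <- mask_iou(seg$mask$mask, truth_band_mask(ss))
  expect_gte(iou, 0.95)
  # determinism: repeated call gives the identical mask
  seg2 <- segment_roi(ss$sample_scan)
  expect_identical(seg$mask$mask, seg2$mask$mask)
})

test_that("a uniformly bright image segments to the full image", {
  t <- seq(0, 2e-6, by = 1e-8)
  rf <- matrix(rep(sin(2 * pi * 5e6 * t), each = 5), nrow = 5)
  seg <- segment_roi(toy_bscan(rf), threshold_db = -26, closing_radius = c(3, 2))
  expect_gte(mean(seg$mask$mask), 0.97) # transform edge effects only
})

test_that("thickness sub-segmentation trims each line from its own ROI top", {
  scan <- toy_bscan(matrix(0.1, 6, 200), sampling_rate = 100e6,
                    sound_speed = 1540)
  m <- matrix(FALSE, 6, 200)
  m[, 51:150] <- TRUE # uniform 100-sample ROI
  seg <- apply_mask(scan, m)
  step_mm <- 1540 / (2 * 100e6) * 1e3
  full_th <- 99 * step_mm

  # thickness >= full ROI: unchanged
  same <- sub_segment_by_thickness(seg, full_th + 1)
  expect_identical(same$mask$mask, m)

  # half thickness: per-line sample count halves within one sample
  half <- sub_segment_by_thickness(seg, full_th / 2)
  counts <- rowSums(half$mask$mask)
  expect_true(all(abs(counts - 50) <= 1))

  # vanishing thickness: only the top surface sample survives
  top <- sub_segment_by_thickness(seg, 1e-9)
  expect_true(all(rowSums(top$mask$mask) == 1))
  expect_true(all(which(top$mask$mask[1, ]) == 51))
})

test_that("closing is extensive for random masks", {
  set.seed(21)
  for (i in 1:200) {
    m <- matrix(stats::runif(24 * 32) < stats::runif(1, 0.05, 0.6), 24, 32)
    cm <- clean_mask(m, c(3, 2))
    expect_true(all(cm[m]))
  }
})
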