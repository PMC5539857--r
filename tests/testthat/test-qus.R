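test_that("incident-amplitude calibration inverts the reflection relation", {
  # V_r = 0.5 off a reflector at 3x the coupling impedance
  expect_equal(calibrate_incident(0.5, Z_w = 1, Z_q = 3), 1.0)
  # perfect-reflector limit: V_i -> V_r
  expect_equal(calibrate_incident(0.5, Z_w = 1, Z_q = 1e12), 0.5,
               tolerance = 1e-9)
  expect_error(calibrate_incident(0.5, Z_w = 1.48, Z_q = 1.48), "matched")
})

test_that("calibrate -> estimate round trip returns the reflector impedance exactly", {
  Z_w <- 1.48
  for (Z in c(1.6, 2.96, 7.4, 13.1)) {
    V_i <- 2.3
    v_echo <- V_i * (Z - Z_w) / (Z + Z_w)
    V_i_hat <- calibrate_incident(v_echo, Z_w = Z_w, Z_q = Z)
    expect_equal(V_i_hat, V_i)
    expect_equal(estimate_impedance(V_i_hat, v_echo, Z_w), Z)
  }
})

test_that("impedance relation reproduces hand-computed cases and rejects unphysical input", {
  expect_identical(estimate_impedance(1, 0, 1.48), 1.48)
  expect_equal(estimate_impedance(1, 1 / 3, 1.48), 2.96)
  expect_equal(estimate_impedance(1, -1 / 3, 1.48), 0.74)
  # soft/hard reflector symmetry about Z_w
  expect_equal(
    estimate_impedance(1, 1 / 3, 1.48) * estimate_impedance(1, -1 / 3, 1.48),
    1.48^2
  )
  expect_error(estimate_impedance(1, 1, 1.48))
  expect_error(estimate_impedance(1, 1.2, 1.48))
})

test_that("attenuation relation reproduces hand-computed cases", {
  expect_equal(estimate_attenuation(1, 1, 5), 0)
  expect_equal(estimate_attenuation(0.1, 1, 5), 2)
  expect_equal(estimate_attenuation(c(1, 0.1), c(1, 1), 5), c(0, 2))
  expect_error(estimate_attenuation(0, 1, 5))
  expect_error(estimate_attenuation(1, -1, 5))
})

test_that("dB and neper attenuation scales stay exactly consistent", {
  expect_equal(db_to_neper(8.686), 1)
  expect_identical(db_to_neper(0), 0)
  expect_equal(db_to_neper(1.86), 1.86 / 8.686)
  est <- attenuation_estimate(c(1.2, 1.86, 2.4))
  expect_identical(est$per_line$a_prime_np_mm, est$per_line$alpha_db_mm / 8.686)
  expect_equal(glance(est)$mean_np_mm, est$mean / 8.686)
})

test_that("gate compensation factor is continuous at zero attenuation", {
  d1 <- 1; d2 <- 3
  lim <- bsc_gate_factor(0, d1, d2)
  expect_equal(lim, 1 / (d2 - d1))
  num <- bsc_gate_factor(1e-9, d1, d2)
  expect_equal(num, lim, tolerance = 1e-6)
  expect_error(bsc_gate_factor(0.1, 3, 1), "d1 < d2")
})

test_that("backscatter of one line follows the adopted grouping", {
  # geometry factor forced to 1: R_q = 1 and 2 pi (1 - cos theta) = 1
  theta <- acos(1 - 1 / (2 * pi))
  fs <- 100e6
  ref <- structure(
    list(waveform = rep(0.5, 400), sampling_rate = fs,
         reflector_impedance = 13.1, reflection_coefficient = 1,
         with_tissue = FALSE, tissue_thickness = NA_real_),
    class = "reference_echo"
  )
  cal <- calibration_set(
    incident_amplitude = 1, reference_echo = ref,
    transducer_half_angle = theta, quartz_reflection_coefficient = 1
  )
  g <- gated_signal(rep(0.5, 400), fs, 0, 400 / fs)
  # equal energies, d2 - d1 = 2 mm, a' -> 0 limit: mu_B = 1 * 1 * 1/2
  expect_equal(estimate_bsc_line(g, cal, 0, 1, 3), 0.5)
  expect_equal(estimate_bsc_line(g, cal, 1e-9, 1, 3), 0.5, tolerance = 1e-6)

  # zero signal and quadratic energy scaling
  g0 <- gated_signal(rep(0, 400), fs, 0, 400 / fs)
  expect_equal(estimate_bsc_line(g0, cal, 0.2, 1, 3), 0)
  g2 <- gated_signal(rep(1.0, 400), fs, 0, 400 / fs)
  expect_equal(
    estimate_bsc_line(g2, cal, 0.2, 1, 3) / estimate_bsc_line(g, cal, 0.2, 1, 3),
    4
  )
})

test_that("per-scan aggregation matches brute-force recomputation of the stored lines", {
  ss <- speckle_scan_set()
  seg <- segment_roi(ss$sample_scan)
  cal <- calibration_from_scan_set(ss)
  z <- estimate_impedance_scan(seg, cal)
  vals <- tidy(z)$impedance_mrayl
  vals <- vals[!is.na(vals)]
  expect_equal(z$mean, mean(vals))
  expect_equal(z$sd, stats::sd(vals) * sqrt((length(vals) - 1) / length(vals)))

  bsc <- estimate_bsc_scan(seg, cal, 1.86)
  mv <- tidy(bsc)$mu_b
  expect_equal(bsc$mean, mean(mv, na.rm = TRUE))
})

test_that("identical lines give zero spread and empty masks are rejected", {
  t <- seq(0, 2e-6, by = 1e-8)
  rf <- matrix(rep(0.3 * sin(2 * pi * 5e6 * t), each = 4), nrow = 4)
  scan <- toy_bscan(rf)
  seg <- apply_mask(scan, matrix(TRUE, 4, length(t)))
  cal <- calibration_set(incident_amplitude = 1)
  z <- estimate_impedance_scan(seg, cal)
  expect_equal(z$sd, 0)
  expect_equal(z$n_skipped, 0)

  seg_empty <- apply_mask(scan, matrix(FALSE, 4, length(t)))
  expect_error(estimate_impedance_scan(seg_empty, cal), "empty")
  expect_error(estimate_bsc_scan(seg_empty, cal, 1.86), "empty")
})

test_that("lines without ROI are skipped and counted, not failed", {
  t <- seq(0, 2e-6, by = 1e-8)
  rf <- matrix(rep(0.3 * sin(2 * pi * 5e6 * t), each = 4), nrow = 4)
  scan <- toy_bscan(rf)
  m <- matrix(TRUE, 4, length(t))
  m[2, ] <- FALSE
  z <- estimate_impedance_scan(apply_mask(scan, m),
                               calibration_set(incident_amplitude = 1))
  expect_equal(z$n_skipped, 1)
  expect_equal(z$n_lines, 3)
  expect_true(is.na(tidy(z)$impedance_mrayl[2]))
})
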