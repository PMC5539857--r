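test_that("single-interface echo arrives at the analytic time of flight", {
  p <- test_pulse()
  for (standoff in c(1.5, 3, 4.5)) {
    ph <- layered_phantom(list(tissue_layer("slab", 1, 2.0)),
      standoff = standoff, coupling_sound_speed = 1480,
      substrate_impedance = 2.0
    )
    b <- simulate_bscan(ph, p, n_lines = 1, seed = 1)
    env <- compute_envelope(b)
    t_peak <- (which.max(env$db[1, ]) - 1) / b$sampling_rate
    t_true <- 2 * standoff * 1e-3 / 1480
    expect_lt(abs(t_peak - t_true), 1 / b$sampling_rate)
  }
})

test_that("a fully matched, scatterer-free phantom yields silent RF", {
  p <- test_pulse()
  ph <- layered_phantom(
    list(tissue_layer("matched", 2, 1.48, sound_speed = 1480)),
    coupling_impedance = 1.48, substrate_impedance = 1.48
  )
  b <- simulate_bscan(ph, p, n_lines = 3, noise_sd = 0, seed = 1)
  expect_true(all(b$rf == 0))
  b_noisy <- simulate_bscan(ph, p, n_lines = 3, noise_sd = 0.01, seed = 1)
  expect_false(all(b_noisy$rf == 0))
  expect_equal(stats::sd(as.vector(b_noisy$rf)), 0.01, tolerance = 0.05)
})

test_that("identical seeds reproduce B-scans and scan sets bit-identically", {
  p <- test_pulse()
  ph <- gi_phantom()
  b1 <- simulate_bscan(ph, p, n_lines = 4, noise_sd = 0.005, seed = 42)
  b2 <- simulate_bscan(ph, p, n_lines = 4, noise_sd = 0.005, seed = 42)
  expect_identical(b1$rf, b2$rf)
  b3 <- simulate_bscan(ph, p, n_lines = 4, noise_sd = 0.005, seed = 43)
  expect_false(identical(b1$rf, b3$rf))
})

test_that("specular echo amplitude follows reflection, transmission and attenuation", {
  p <- test_pulse()
  # two-layer phantom, transmission off: second-interface amplitude is
  # R2 * 10^(-2 alpha d / 20)
  ph <- layered_phantom(
    list(tissue_layer("slab", 2, 1.8, attenuation = 1.5, sound_speed = 1540)),
    coupling_impedance = 1.48, substrate_impedance = 2.2, standoff = 1
  )
  b <- simulate_bscan(ph, p, n_lines = 1, seed = 1, transmission = FALSE)
  env <- qusim:::envelope_mag(b$rf[1, ])
  r1 <- (1.8 - 1.48) / (1.8 + 1.48)
  r2 <- (2.2 - 1.8) / (2.2 + 1.8)
  i1 <- round(2 * 1e-3 / 1480 * b$sampling_rate) + 1
  i2 <- i1 + round(2 * 2e-3 / 1540 * b$sampling_rate)
  w <- 30
  a1 <- max(env[(i1 - w):(i1 + w)])
  a2 <- max(env[(i2 - w):(i2 + w)])
  expect_equal(a1, r1, tolerance = 1e-6)
  expect_equal(a2, r2 * 10^(-2 * 1.5 * 2 / 20), tolerance = 1e-6)
})

test_that("speckle amplitude scales with the square root of backscatter strength", {
  p <- test_pulse()
  mk <- function(bs, seed) {
    ph <- layered_phantom(
      list(tissue_layer("t", 2, 1.48, backscatter_strength = bs,
                        scatterer_density = 200)),
      substrate_impedance = 1.48
    )
    simulate_bscan(ph, p, n_lines = 50, seed = seed, transmission = FALSE)
  }
  b1 <- mk(4e-4, 1)
  b2 <- mk(16e-4, 2)
  fs <- b1$sampling_rate
  band <- (round(2 * 2.3e-3 / 1500 * fs)):(round(2 * 3.2e-3 / 1500 * fs))
  amp1 <- mean(abs(b1$rf[, band]))
  amp2 <- mean(abs(b2$rf[, band]))
  expect_equal(amp2 / amp1, 2, tolerance = 0.07)
})

test_that("reference pair obeys the round-trip attenuation law", {
  p <- test_pulse()
  lossless <- tissue_layer("s", 5, 1.6, attenuation = 0)
  pair0 <- simulate_reference_pair(lossless, pulse = p, transmission = FALSE)
  expect_equal(echo_amplitude(pair0$with_tissue),
               echo_amplitude(pair0$without), tolerance = 1e-9)

  lossy <- tissue_layer("s", 5, 1.6, attenuation = 2)
  pair <- simulate_reference_pair(lossy, pulse = p, transmission = FALSE)
  ratio <- echo_amplitude(pair$with_tissue) / echo_amplitude(pair$without)
  expect_equal(ratio, 0.1, tolerance = 1e-9) # 10^(-2*2*5/20)

  matched <- simulate_reference_pair(lossless, quartz_impedance = 1.48, pulse = p)
  expect_equal(echo_amplitude(matched$without), 0)
})

test_that("default scan-set geometry spans 30 mm in 61 lines and records ground truth", {
  ss <- speckle_scan_set()
  expect_equal(nrow(ss$sample_scan$rf), 61)
  expect_equal(ss$sample_scan$line_pitch, 0.5)
  expect_equal(ss$sample_scan$scan_length, 30)
  expect_equal(ss$ground_truth$layers[[1]]$attenuation, 1.86)
  gt <- tidy(ss$ground_truth)
  expect_equal(gt$attenuation_db_mm, c(1.86, 1.86))
  # members share one clock
  expect_equal(ss$reference_no_tissue$sampling_rate, ss$sample_scan$sampling_rate)
})

test_that("scan-set assembly rejects inconsistent sampling rates", {
  ss <- specular_scan_set()
  bad <- ss$reference_no_tissue
  bad$sampling_rate <- bad$sampling_rate / 2
  expect_error(
    scan_set(ss$sample_scan, bad, ss$reference_with_tissue,
             ss$quartz_scan_for_incident, ss$ground_truth),
    "sampling rates"
  )
})
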