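test_that("TER arithmetic is the blank-corrected, area-scaled meter reading", {
  expect_equal(ter(800, 100, 1.0), 700)
  expect_equal(ter(100, 100, 1.0), 0)
  # linear in area, additive in resistance offsets
  expect_equal(ter(800, 100, 2.0), 2 * ter(800, 100, 1.0))
  expect_equal(ter(800 + 50, 100 + 50, 1.0), ter(800, 100, 1.0))
  expect_error(ter(800, 100, 0))
})

test_that("barrier readiness window is 500-1000 inclusive", {
  expect_true(barrier_ready(750))
  expect_true(barrier_ready(500))
  expect_true(barrier_ready(1000))
  expect_false(barrier_ready(499.9))
  expect_false(barrier_ready(1000.1))
})

flat_series <- function(ter_value = 700, n = 20, area = 1.0, blank = 100) {
  tibble::tibble(
    well_id = "w1", condition = "MB_only",
    time_min = seq(0, by = 0.5, length.out = n),
    resistance_ohm = ter_value / area + blank,
    blank_resistance_ohm = blank, membrane_area_cm2 = area
  )
}

test_that("percent drop reproduces the worked fractions and is scale-invariant", {
  s <- flat_series()
  expect_equal(percent_drop(s, baseline_window = 3)$percent_drop, 0)

  dip <- flat_series(n = 30)
  dip$resistance_ohm[15] <- 700 * 0.9448 + 100
  expect_equal(percent_drop(dip, 5)$percent_drop, 5.52, tolerance = 1e-9)
  dip2 <- flat_series(n = 30)
  dip2$resistance_ohm[15] <- 700 * 0.9706 + 100
  expect_equal(percent_drop(dip2, 5)$percent_drop, 2.94, tolerance = 1e-9)

  # multiplying the TER trace by any positive constant leaves the drop alone
  scaled <- dip
  scaled$resistance_ohm <- (scaled$resistance_ohm - 100) * 3.7 + 100
  expect_equal(percent_drop(scaled, 5)$percent_drop,
               percent_drop(dip, 5)$percent_drop)

  expect_error(percent_drop(dip, 0), "baseline")
  expect_error(percent_drop(dip[1, ], 5), "two samples")
})

test_that("recovery time finds the first return to baseline, or reports none", {
  never <- flat_series(n = 30)
  never$resistance_ohm[15:30] <- 0.5 * 700 + 100
  expect_true(is.na(recovery_time(never, 700)))

  spec <- ter_condition("US_only", drop_fraction = 0.0552, noise_sd = 0,
                        n_wells = 1, drop_cv = 0, recovery_time = 5.5)
  s <- generate_ter_series(spec, duration = 15, insonation_start = 5, seed = 1)
  pd <- percent_drop(s, 5)
  expect_equal(pd$percent_drop, 5.52, tolerance = 1e-6)
  expect_gte(pd$recovery_min - 5, 5)
  expect_lte(pd$recovery_min - 5, 6)

  flat <- flat_series()
  expect_equal(recovery_time(flat, 700), flat$time_min[2])
})

test_that("TER generator honours drop depth, flatness and determinism", {
  zero <- generate_ter_series(
    ter_condition("MB_only", drop_fraction = 0, noise_sd = 0, n_wells = 2),
    seed = 3
  )
  y <- ter(zero$resistance_ohm, zero$blank_resistance_ohm, zero$membrane_area_cm2)
  expect_true(all(y == 700))

  a <- generate_ter_series(ter_condition("US_only", drop_fraction = 0.03), seed = 9)
  b <- generate_ter_series(ter_condition("US_only", drop_fraction = 0.03), seed = 9)
  expect_identical(a, b)
})

test_that("condition summaries use the fixed arm ordering and exact truths at zero noise", {
  specs <- list(
    ter_condition("US_plus_MB", drop_fraction = 0.0552, noise_sd = 0,
                  drop_cv = 0, n_wells = 3),
    ter_condition("MB_only", drop_fraction = 0, noise_sd = 0, drop_cv = 0,
                  n_wells = 3),
    ter_condition("US_only", drop_fraction = 0.0294, noise_sd = 0, drop_cv = 0,
                  n_wells = 3)
  )
  series <- generate_ter_series(specs, seed = 4)
  s <- summarize_conditions(series)
  expect_equal(s$condition, c("MB_only", "US_only", "US_plus_MB"))
  expect_equal(s$mean_percent_drop, c(0, 2.94, 5.52), tolerance = 1e-6)
  expect_equal(s$sd_percent_drop, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(s$n_wells, c(3, 3, 3))

  bad <- series
  bad$condition[1] <- "mystery"
  expect_error(summarize_conditions(bad), "Unknown condition")
})
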