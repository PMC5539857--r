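test_that("a single fitted impedance reproduces the measured input-power column", {
  tab <- table3_fixture()
  # least-squares fit of W = V^2/(8Z) through the measured pairs
  fit <- stats::lm(w_input_mw ~ 0 + I(vpp^2), data = tab)
  z_fit <- 1000 / (8 * stats::coef(fit)[[1]])
  expect_equal(focused_transducer_impedance, z_fit, tolerance = 0.01)
  w <- electrical_input_power(tab$vpp)
  # last-printed-digit tolerance per row: 0.01 below 10 mW, 0.1 below 100, 1 above
  tol <- ifelse(tab$w_input_mw < 10, 0.01, ifelse(tab$w_input_mw < 100, 0.1, 1))
  expect_true(all(abs(w - tab$w_input_mw) <= tol + 1e-9))
})

test_that("input power is quadratic in drive voltage and zero at zero drive", {
  expect_equal(electrical_input_power(0), 0)
  expect_equal(electrical_input_power(10) / electrical_input_power(5), 4)
  expect_equal(electrical_input_power(10), 254, tolerance = 0.002)
  expect_error(electrical_input_power(-1))
})

test_that("efficiency reproduces the published cells", {
  expect_equal(electroacoustic_efficiency(51.0, 91.4), 55.8, tolerance = 0.002)
  expect_equal(electroacoustic_efficiency(19.9, 40.6), 49.0, tolerance = 0.002)
  expect_equal(electroacoustic_efficiency(0, 42), 0)
  expect_error(electroacoustic_efficiency(10, 0))
})

test_that("spatial-average intensity uses the -6 dB beam disc", {
  expect_equal(spatial_average_intensity(153, 2.70), 0.153 / (pi * 0.135^2),
               tolerance = 1e-12)
  expect_equal(spatial_average_intensity(153, 2.70), 2.67, tolerance = 0.005)
  expect_equal(spatial_average_intensity(71.3, 2.70), 1.25, tolerance = 0.005)
  expect_equal(spatial_average_intensity(0, 2.70), 0)
  # linear in power at fixed diameter
  expect_equal(spatial_average_intensity(100, 2.7) / spatial_average_intensity(50, 2.7), 2)
  expect_error(spatial_average_intensity(10, 0))
})

test_that("mechanical index is the undereated regulatory form", {
  expect_equal(mechanical_index(34.7, 4), 0.0347 / 2)
  expect_equal(mechanical_index(34.7, 4), 0.017, tolerance = 0.03)
  expect_equal(mechanical_index(22.9, 4), 0.011, tolerance = 0.05)
  # linear in pressure at fixed frequency
  expect_equal(mechanical_index(200, 4) / mechanical_index(100, 4), 2)
  expect_error(mechanical_index(-1, 4))
})

test_that("radiation-force-balance conversion applies mass x g x c(T)", {
  expect_equal(rfb_power(0), 0)
  expect_equal(rfb_power(153, calibration_factor = 1), 153)
  # independent oracle: m g c with c(20 C) = 1482.3 m/s
  expect_equal(rfb_power(0.0105, temperature_c = 20), 0.0105 * 9.81 * 1482.3,
               tolerance = 1e-4)
  expect_equal(rfb_power(0.0105), 152.7, tolerance = 0.001)
})

test_that("the derived output table reproduces every derivable published cell", {
  tab3 <- table3_fixture()
  out <- build_output_table(tab3)
  # rows without measurable acoustic power carry absent efficiency/intensity
  expect_true(all(is.na(out$efficiency_pct[1:2])))
  expect_true(all(is.na(out$intensity_w_cm2[1:2])))
  expect_false(anyNA(out$mech_index))

  expect_true(all(abs(out$efficiency_pct[3:10] - tab3$efficiency_pct[3:10]) <= 0.1 + 1e-9))
  expect_true(all(abs(out$intensity_w_cm2[3:10] - tab3$intensity_w_cm2[3:10]) <= 0.01 + 1e-9))
  expect_true(all(abs(out$mech_index - tab3$mech_index) <= 0.001 + 1e-9))

  s <- glance(out)
  expect_equal(s$efficiency_mean_pct, 54, tolerance = 0.01)
  expect_equal(s$efficiency_min_pct, 37.2, tolerance = 0.005)
  expect_equal(s$efficiency_max_pct, 60.3, tolerance = 0.005)
  expect_equal(s$p_ac_min_mw, 8.5)
  expect_equal(s$p_ac_max_mw, 153)
})

test_that("the table builder validates alignment, flags energy violations, handles empty input", {
  expect_error(build_output_table(c(1, 2), p_ac = c(1, 2, 3)), "align")
  empty <- build_output_table(numeric(0))
  expect_equal(nrow(empty), 0)
  expect_s3_class(empty, "transducer_output_table")
  expect_warning(out <- build_output_table(1, p_ac = 10, pressure = 10),
                 "efficiency > 100")
  expect_false(out$energy_ok)
})
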