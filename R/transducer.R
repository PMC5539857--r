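#' Default drive electrical impedance for the miniature focused transducer
#'
#' Electrical impedance magnitude (Ohm) of the 4 MHz perforated PZ26 bowl at
#' its drive frequency, obtained once by least squares from the ten published
#' (peak-to-peak voltage, electrical input power) pairs of the transducer
#' characterization bundled with the package; a single constant reproduces the
#' whole input-power column. Shipped as a documented constant rather than
#' hard-coded into the power formula.
#'
#' @format A single number, 49.25 Ohm.
#' @export
focused_transducer_impedance <- 49.25

#' Electrical input power of a sinusoidal drive
#'
#' Mean power of a sinusoid of peak-to-peak amplitude `vpp` into a resistive
#' load: `W_input = V_pp^2 / (8 Z)`, reported in mW. Quadratic in the drive
#' voltage.
#'
#' @param vpp Peak-to-peak drive voltage, V (vectorised; >= 0).
#' @param impedance Electrical impedance magnitude at the drive frequency,
#'   Ohm.
#' @return Input power in mW.
#' @examples
#' electrical_input_power(10) # ~253.8 mW
#' @export
electrical_input_power <- function(vpp, impedance = focused_transducer_impedance) {
  if (!is.numeric(vpp) || any(vpp < 0)) abort("`vpp` must be >= 0.")
  assert_scalar_number(impedance, "impedance", positive = TRUE)
  vpp^2 / (8 * impedance) * 1000
}

#' Electroacoustic efficiency
#'
#' Ratio of acoustic output power to electrical input power, in percent.
#'
#' @param p_ac Acoustic output power, mW (>= 0, vectorised; NA propagates).
#' @param w_input Electrical input power, mW (> 0).
#' @return Efficiency in percent.
#' @examples
#' electroacoustic_efficiency(51.0, 91.4) # 55.8
#' @export
electroacoustic_efficiency <- function(p_ac, w_input) {
  if (any(!is.na(w_input) & w_input <= 0)) abort("`w_input` must be > 0.")
  if (any(!is.na(p_ac) & p_ac < 0)) abort("`p_ac` must be >= 0.")
  100 * p_ac / w_input
}

#' Spatial-average intensity over the -6 dB beam disc
#'
#' Acoustic power divided by the area of the -6 dB beam disc,
#' `pi (beam_diameter / 2)^2`, in W/cm^2. Linear in the power at fixed beam
#' diameter.
#'
#' @param p_ac Acoustic output power, mW (>= 0, vectorised; NA propagates).
#' @param beam_diameter -6 dB beam diameter, mm (> 0).
#' @return Intensity in W/cm^2.
#' @examples
#' spatial_average_intensity(153, 2.70) # ~2.67
#' @export
spatial_average_intensity <- function(p_ac, beam_diameter) {
  if (any(!is.na(p_ac) & p_ac < 0)) abort("`p_ac` must be >= 0.")
  assert_scalar_number(beam_diameter, "beam_diameter", positive = TRUE)
  area_cm2 <- pi * (beam_diameter / 20)^2 # mm diameter -> cm radius
  (p_ac / 1000) / area_cm2
}

#' Mechanical index
#'
#' `MI = peak pressure (MPa) / sqrt(frequency (MHz))` - the regulatory
#' definition with the derating factor omitted, appropriate for water-tank
#' characterization. Linear in pressure at fixed frequency.
#'
#' @param pressure Peak pressure in kPa (>= 0, vectorised).
#' @param frequency Drive frequency in MHz (> 0).
#' @return Dimensionless mechanical index.
#' @examples
#' mechanical_index(34.7, 4) # ~0.017
#' @export
mechanical_index <- function(pressure, frequency) {
  if (any(!is.na(pressure) & pressure < 0)) abort("`pressure` must be >= 0.")
  assert_scalar_number(frequency, "frequency", positive = TRUE)
  (pressure / 1000) / sqrt(frequency)
}

#' Acoustic power from a radiation-force-balance reading
#'
#' Converts the equivalent mass registered by a radiation force balance into
#' acoustic power: `P_ac = mass x calibration factor`. When no
#' manufacturer-supplied, temperature-specific factor is given, the physics
#' default `g x c_water(T)` is used (plane-wave absorbing target), with the
#' speed of sound in pure water from the Marczak polynomial.
#'
#' @param equivalent_mass Equivalent mass in g (>= 0, vectorised).
#' @param calibration_factor Calibration factor in mW/g; `NULL` selects the
#'   physics default for `temperature_c`.
#' @param temperature_c Water temperature in Celsius for the default factor.
#' @return Acoustic power in mW.
#' @examples
#' rfb_power(0.0105) # ~152.7 mW at 20 C
#' @export
rfb_power <- function(equivalent_mass, calibration_factor = NULL,
                      temperature_c = 20) {
  if (any(equivalent_mass < 0)) abort("`equivalent_mass` must be >= 0.")
  if (is.null(calibration_factor)) {
    calibration_factor <- 9.81 * water_sound_speed(temperature_c) # mW per g
  }
  assert_scalar_number(calibration_factor, "calibration_factor", positive = TRUE)
  equivalent_mass * calibration_factor
}

# speed of sound in pure water (m/s), Marczak (1997) polynomial, 0-95 C
water_sound_speed <- function(temperature_c) {
  t <- temperature_c
  1.402385e3 + 5.038813 * t - 5.799136e-2 * t^2 + 3.287156e-4 * t^3 -
    1.398845e-6 * t^4 + 2.787860e-9 * t^5
}

#' Derived acoustic-output table for a focused transducer
#'
#' Builds the full characterization table from the measured drive conditions:
#' electrical input power from the drive voltage, electroacoustic efficiency,
#' spatial-average intensity over the -6 dB beam disc, and mechanical index.
#' Rows without a measurable acoustic power (the radiation force balance
#' cannot resolve the lowest drive levels) carry `NA` efficiency and
#' intensity. Any row whose efficiency exceeds 100% while `p_ac <= w_input`
#' should hold is flagged (`energy_ok = FALSE`) and a warning is raised, never
#' silently accepted.
#'
#' @param drives Peak-to-peak drive voltages (numeric vector), or a data frame
#'   with columns `vpp` and optionally `p_ac_mw`, `pressure_kpa`.
#' @param p_ac Acoustic output powers, mW, aligned with `drives` (NA where not
#'   measurable). Ignored when `drives` is a data frame carrying `p_ac_mw`.
#' @param pressure Peak pressures, kPa, aligned with `drives`. Ignored when
#'   `drives` carries `pressure_kpa`.
#' @param beam_diameter -6 dB beam diameter, mm.
#' @param frequency Drive frequency, MHz.
#' @param impedance Electrical impedance magnitude, Ohm.
#' @return A tibble of class `transducer_output_table` with columns `vpp`,
#'   `w_input_mw`, `p_ac_mw`, `efficiency_pct`, `pressure_kpa`,
#'   `beam_diameter_mm`, `intensity_w_cm2`, `mech_index`, `energy_ok`.
#'   [glance()] returns the efficiency min/max/mean and acoustic power range.
#' @export
build_output_table <- function(drives, p_ac = NULL, pressure = NULL,
                               beam_diameter = 2.70, frequency = 4,
                               impedance = focused_transducer_impedance) {
  if (is.data.frame(drives)) {
    if (!"vpp" %in% names(drives)) abort("Drive data frame needs a `vpp` column.")
    p_ac <- if ("p_ac_mw" %in% names(drives)) drives$p_ac_mw else p_ac
    pressure <- if ("pressure_kpa" %in% names(drives)) drives$pressure_kpa else pressure
    drives <- drives$vpp
  }
  n <- length(drives)
  if (n == 0) {
    out <- tibble(
      vpp = numeric(0), w_input_mw = numeric(0), p_ac_mw = numeric(0),
      efficiency_pct = numeric(0), pressure_kpa = numeric(0),
      beam_diameter_mm = numeric(0), intensity_w_cm2 = numeric(0),
      mech_index = numeric(0), energy_ok = logical(0)
    )
    class(out) <- c("transducer_output_table", class(out))
    return(out)
  }
  p_ac <- p_ac %||% rep(NA_real_, n)
  pressure <- pressure %||% rep(NA_real_, n)
  if (length(p_ac) != n || length(pressure) != n) {
    abort("`p_ac` and `pressure` must align with `drives`.")
  }
  w_in <- electrical_input_power(drives, impedance)
  eff <- electroacoustic_efficiency(p_ac, w_in)
  out <- tibble(
    vpp = as.numeric(drives),
    w_input_mw = w_in,
    p_ac_mw = as.numeric(p_ac),
    efficiency_pct = eff,
    pressure_kpa = as.numeric(pressure),
    beam_diameter_mm = beam_diameter,
    intensity_w_cm2 = spatial_average_intensity(p_ac, beam_diameter),
    mech_index = mechanical_index(pressure, frequency),
    energy_ok = is.na(eff) | eff <= 100
  )
  if (any(!out$energy_ok)) {
    warn("Some rows report acoustic power above electrical input power (efficiency > 100%).")
  }
  class(out) <- c("transducer_output_table", class(out))
  out
}

#' @describeIn build_output_table Efficiency min/max/mean (over rows with a
#'   measured acoustic power) and the acoustic power range.
#' @param x A `transducer_output_table`.
#' @param ... Unused.
#' @method glance transducer_output_table
#' @export
glance.transducer_output_table <- function(x, ...) {
  eff <- x$efficiency_pct[!is.na(x$efficiency_pct)]
  p <- x$p_ac_mw[!is.na(x$p_ac_mw)]
  tibble(
    n_rows = nrow(x), n_measured = length(eff),
    efficiency_min_pct = if (length(eff)) min(eff) else NA_real_,
    efficiency_max_pct = if (length(eff)) max(eff) else NA_real_,
    efficiency_mean_pct = if (length(eff)) mean(eff) else NA_real_,
    p_ac_min_mw = if (length(p)) min(p) else NA_real_,
    p_ac_max_mw = if (length(p)) max(p) else NA_real_
  )
}
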