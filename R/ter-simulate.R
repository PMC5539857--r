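#' TER condition specification
#'
#' Describes one arm of the insonation experiment on an epithelial monolayer:
#' microbubbles only, ultrasound only, or ultrasound with microbubbles.
#'
#' @param condition One of `"MB_only"`, `"US_only"`, `"US_plus_MB"`.
#' @param baseline_ter Baseline TER in Ohm cm^2 (500-1000 is the acceptable
#'   barrier-function window for a small-intestine model).
#' @param drop_fraction Mean fractional TER drop at insonation, in `[0, 1)`.
#' @param recovery_time Minutes after insonation at which the TER has returned
#'   to baseline (within the recovery tolerance).
#' @param noise_sd Additive measurement noise on TER, Ohm cm^2.
#' @param n_wells Number of replicate wells.
#' @param drop_cv Well-to-well coefficient of variation of the drop fraction
#'   (biological variability; default 0.2).
#' @return A `ter_condition` list.
#' @export
ter_condition <- function(condition = c("MB_only", "US_only", "US_plus_MB"),
                          baseline_ter = 700, drop_fraction = 0,
                          recovery_time = 5.5, noise_sd = 2, n_wells = 3,
                          drop_cv = 0.2) {
  condition <- match.arg(condition)
  assert_scalar_number(baseline_ter, "baseline_ter", positive = TRUE)
  assert_scalar_number(drop_fraction, "drop_fraction", nonneg = TRUE)
  if (drop_fraction >= 1) abort("`drop_fraction` must be < 1.")
  assert_scalar_number(recovery_time, "recovery_time", positive = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  assert_scalar_number(drop_cv, "drop_cv", nonneg = TRUE)
  structure(
    list(
      condition = condition, baseline_ter = baseline_ter,
      drop_fraction = drop_fraction, recovery_time = recovery_time,
      noise_sd = noise_sd, n_wells = as.integer(n_wells), drop_cv = drop_cv
    ),
    class = "ter_condition"
  )
}

#' Generate synthetic TER time series
#'
#' Each well holds a noisy baseline, a dip of (well-specific) fractional depth
#' beginning at `insonation_start`, and an exponential return that re-attains
#' baseline within the recovery tolerance by
#' `insonation_start + recovery_time`. TER is reported through its components
#' (meter resistance, blank-insert resistance, membrane area) so the analysis
#' side exercises the full TER arithmetic.
#'
#' @param spec A [ter_condition()] (or a list of them, concatenated).
#' @param duration Total duration in minutes.
#' @param sampling_interval Sampling interval in minutes.
#' @param insonation_start Start of insonation in minutes; must lie on the
#'   sampling grid for the programmed minimum to be observed exactly.
#' @param seed Integer seed.
#' @param blank_resistance Blank-insert resistance, Ohm.
#' @param membrane_area Insert membrane area, cm^2 (default 1.13, 12-well
#'   format).
#' @param recovery_tolerance Fractional distance from baseline at which the
#'   series counts as recovered (default 0.01).
#' @return A tibble with columns `well_id`, `condition`, `time_min`,
#'   `resistance_ohm`, `blank_resistance_ohm`, `membrane_area_cm2`.
#' @examples
#' ts <- generate_ter_series(ter_condition("US_only", drop_fraction = 0.0294),
#'   seed = 1)
#' @export
generate_ter_series <- function(spec, duration = 15, sampling_interval = 0.25,
                                insonation_start = 5, seed = 1,
                                blank_resistance = 100, membrane_area = 1.13,
                                recovery_tolerance = 0.01) {
  if (inherits(spec, "ter_condition")) spec <- list(spec)
  stopifnot(all(vapply(spec, inherits, logical(1), "ter_condition")))
  if (!(duration > insonation_start && insonation_start >= 0)) {
    abort("Require duration > insonation_start >= 0.")
  }
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = sampling_interval)
  purrr::map_dfr(spec, function(sp) {
    purrr::map_dfr(seq_len(sp$n_wells), function(w) {
      drop_w <- sp$drop_fraction
      if (sp$drop_cv > 0 && sp$drop_fraction > 0) {
        drop_w <- max(0, min(0.99, stats::rnorm(1, sp$drop_fraction,
                                                sp$drop_cv * sp$drop_fraction)))
      }
      ter <- rep(sp$baseline_ter, length(times))
      if (drop_w > 0) {
        post <- times >= insonation_start
        # time constant chosen so the dip passes within recovery_tolerance of
        # baseline exactly recovery_time minutes after insonation
        tau <- if (drop_w > recovery_tolerance) {
          sp$recovery_time / log(drop_w / recovery_tolerance)
        } else {
          sp$recovery_time / 3
        }
        dt <- times[post] - insonation_start
        ter[post] <- sp$baseline_ter * (1 - drop_w * exp(-dt / tau))
      }
      if (sp$noise_sd > 0) ter <- ter + stats::rnorm(length(ter), 0, sp$noise_sd)
      tibble(
        well_id = sprintf("%s_w%02d", sp$condition, w),
        condition = sp$condition,
        time_min = times,
        resistance_ohm = ter / membrane_area + blank_resistance,
        blank_resistance_ohm = blank_resistance,
        membrane_area_cm2 = membrane_area
      )
    })
  })
}
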