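#' Calibration constants for QUS estimation
#'
#' Houses the quantities the per-line estimators need: coupling and reflector
#' impedances, the incident amplitude (or the quartz echo it is calibrated
#' from), the reference echo used for backscatter normalisation, and the
#' transducer geometry.
#'
#' @param coupling_impedance Imaging-medium impedance Z_w, MRayl (default
#'   1.48, water/dPBS).
#' @param quartz_impedance Reference reflector impedance, MRayl (default 13.1,
#'   fused quartz).
#' @param incident_amplitude Incident wave amplitude V_i in linear units; if
#'   `NULL` it is calibrated from `quartz_echo` via [calibrate_incident()].
#' @param quartz_echo Optional `reference_echo` from the bare quartz flat.
#' @param reference_echo `reference_echo` whose full-window energy normalises
#'   the backscatter coefficient (the bare-quartz echo is the usual choice).
#' @param transducer_half_angle Half-angle subtended by the transducer face at
#'   the focal point, radians. Default `asin(2.5/15)` (5 mm aperture, 15 mm
#'   radius of curvature).
#' @param quartz_reflection_coefficient Reflection coefficient R_q of the
#'   reference reflector; computed from the impedances when `NULL`.
#' @param population_sd Use population (n) rather than sample (n-1) standard
#'   deviation for the per-scan error bars (default TRUE).
#' @return A `calibration_set` list.
#' @export
calibration_set <- function(coupling_impedance = 1.48, quartz_impedance = 13.1,
                            incident_amplitude = NULL, quartz_echo = NULL,
                            reference_echo = NULL,
                            transducer_half_angle = asin(2.5 / 15),
                            quartz_reflection_coefficient = NULL,
                            population_sd = TRUE) {
  assert_scalar_number(coupling_impedance, "coupling_impedance", positive = TRUE)
  assert_scalar_number(quartz_impedance, "quartz_impedance", positive = TRUE)
  assert_scalar_number(transducer_half_angle, "transducer_half_angle", positive = TRUE)
  if (transducer_half_angle >= pi / 2) {
    abort("`transducer_half_angle` must lie in (0, pi/2).")
  }
  if (is.null(incident_amplitude)) {
    if (!is.null(quartz_echo)) {
      incident_amplitude <- calibrate_incident(
        quartz_echo, coupling_impedance, quartz_impedance
      )
    }
  } else {
    assert_scalar_number(incident_amplitude, "incident_amplitude", positive = TRUE)
  }
  if (is.null(quartz_reflection_coefficient)) {
    quartz_reflection_coefficient <- (quartz_impedance - coupling_impedance) /
      (quartz_impedance + coupling_impedance)
  }
  structure(
    list(
      coupling_impedance = coupling_impedance,
      quartz_impedance = quartz_impedance,
      incident_amplitude = incident_amplitude,
      reference_echo = reference_echo,
      transducer_half_angle = transducer_half_angle,
      quartz_reflection_coefficient = quartz_reflection_coefficient,
      population_sd = population_sd
    ),
    class = "calibration_set"
  )
}

#' Calibration set from a simulated scan set
#'
#' @param ss A `scan_set`.
#' @param ... Overrides passed to [calibration_set()].
#' @return A `calibration_set` whose incident amplitude is calibrated from the
#'   scan set's bare-quartz echo and whose reference echo is the same echo.
#' @export
calibration_from_scan_set <- function(ss, ...) {
  stopifnot(inherits(ss, "scan_set"))
  calibration_set(
    coupling_impedance = ss$ground_truth$coupling_impedance,
    quartz_impedance = ss$quartz_scan_for_incident$reflector_impedance,
    quartz_echo = ss$quartz_scan_for_incident,
    reference_echo = ss$quartz_scan_for_incident,
    ...
  )
}

#' Calibrate the incident amplitude from a quartz-flat echo
#'
#' Inverts the impedance relation for the incident amplitude using a reflector
#' of known impedance: `V_i = V_r_quartz (Z_q + Z_w) / (Z_q - Z_w)`.
#'
#' @param quartz_echo A `reference_echo` from the bare reflector, or its peak
#'   envelope amplitude as a bare number.
#' @param Z_w Coupling-medium impedance, MRayl.
#' @param Z_q Reflector impedance, MRayl; defaults to the echo's recorded
#'   reflector impedance.
#' @return Incident amplitude V_i (linear units).
#' @examples
#' calibrate_incident(0.5, Z_w = 1, Z_q = 3) # 1.0
#' @export
calibrate_incident <- function(quartz_echo, Z_w, Z_q = NULL) {
  if (inherits(quartz_echo, "reference_echo")) {
    if (is.null(Z_q)) Z_q <- quartz_echo$reflector_impedance
    v <- echo_amplitude(quartz_echo)
  } else {
    v <- quartz_echo
    if (is.null(Z_q)) abort("`Z_q` is required when passing a bare amplitude.")
  }
  assert_scalar_number(Z_w, "Z_w", positive = TRUE)
  assert_scalar_number(Z_q, "Z_q", positive = TRUE)
  if (Z_q == Z_w) {
    abort("Z_q equals Z_w: a matched reflector returns no echo, calibration is impossible.")
  }
  v * (Z_q + Z_w) / (Z_q - Z_w)
}

#' Acoustic impedance from incident and reflected amplitudes
#'
#' `Z_t = Z_w (V_i + V_r) / (V_i - V_r)`: the normal-incidence reflection
#' relation solved for the unknown impedance. `V_r = 0` returns `Z_w` exactly;
#' negative `V_r` (phase-inverted echo from a softer medium) gives
#' `Z_t < Z_w`.
#'
#' @param V_i Incident amplitude (linear units, > 0).
#' @param V_r Reflected amplitude (linear units, may be vectorised); must
#'   satisfy `|V_r| < V_i`.
#' @param Z_w Coupling-medium impedance, MRayl.
#' @return Tissue impedance in MRayl (vectorised over `V_r`).
#' @examples
#' estimate_impedance(1, 1 / 3, 1.48) # 2.96
#' @export
estimate_impedance <- function(V_i, V_r, Z_w) {
  assert_scalar_number(V_i, "V_i", positive = TRUE)
  assert_scalar_number(Z_w, "Z_w", positive = TRUE)
  if (!is.numeric(V_r) || any(!is.finite(V_r))) abort("`V_r` must be finite numeric.")
  if (any(abs(V_r) >= V_i)) {
    abort("|V_r| must be smaller than V_i (sub-unity physical reflection).")
  }
  Z_w * (V_i + V_r) / (V_i - V_r)
}

#' Per-line acoustic impedance of a segmented scan
#'
#' For each A-line with a non-empty ROI, takes the reflected amplitude `V_r`
#' as the peak envelope of the ROI top-surface echo (a short window below the
#' ROI top), applies the impedance relation, and aggregates the per-line
#' values into a mean and standard deviation across lines. Lines without an
#' ROI are skipped and counted.
#'
#' @param segmented A `segmented_scan`.
#' @param cal A [calibration_set()] with a resolved incident amplitude.
#' @param surface_window_mm Length of the window below the per-line ROI top
#'   within which the surface-echo envelope peak is picked (default 0.2 mm).
#' @return A `qus_impedance` object; see [tidy.qus_impedance()] and
#'   [glance.qus_impedance()].
#' @export
estimate_impedance_scan <- function(segmented, cal, surface_window_mm = 0.2) {
  stopifnot(inherits(segmented, "segmented_scan"), inherits(cal, "calibration_set"))
  if (is.null(cal$incident_amplitude)) {
    abort("Calibration set has no incident amplitude; supply one or a quartz echo.")
  }
  scan <- segmented$source
  m <- segmented$mask$mask
  if (!any(m)) abort("Mask is empty on all lines.")
  fs <- scan$sampling_rate
  cs <- scan$sound_speed_assumed
  win_samples <- max(1L, round(surface_window_mm * 1e-3 * 2 * fs / cs))
  per_line <- purrr::map_dfr(seq_len(nrow(m)), function(li) {
    idx <- which(m[li, ])
    if (length(idx) == 0) {
      return(tibble(line = li, v_r = NA_real_, impedance_mrayl = NA_real_))
    }
    top <- min(idx)
    w <- top:min(top + win_samples - 1L, ncol(m))
    env <- envelope_mag(scan$rf[li, ])
    v_r <- max(env[intersect(w, idx)])
    z <- estimate_impedance(cal$incident_amplitude, v_r, cal$coupling_impedance)
    tibble(line = li, v_r = v_r, impedance_mrayl = z)
  })
  vals <- per_line$impedance_mrayl[!is.na(per_line$impedance_mrayl)]
  structure(
    list(
      per_line = per_line,
      mean = mean(vals),
      sd = agg_sd(vals, cal$population_sd),
      n_lines = length(vals),
      n_skipped = sum(is.na(per_line$impedance_mrayl)),
      segmentation_thickness = segmented$segmentation_thickness %||% NA_real_
    ),
    class = "qus_impedance"
  )
}

agg_sd <- function(x, population = TRUE) {
  n <- length(x)
  if (n <= 1) return(0)
  s <- stats::sd(x)
  if (population) s * sqrt((n - 1) / n) else s
}

#' @export
print.qus_impedance <- function(x, ...) {
  cat(sprintf(
    "<qus_impedance> Z_t = %.3f +/- %.3f MRayl over %d lines (%d skipped)\n",
    x$mean, x$sd, x$n_lines, x$n_skipped
  ))
  invisible(x)
}

#' @describeIn estimate_impedance_scan Per-line tibble (`line`, `v_r`,
#'   `impedance_mrayl`).
#' @param x A `qus_impedance`.
#' @param ... Unused.
#' @method tidy qus_impedance
#' @export
tidy.qus_impedance <- function(x, ...) x$per_line

#' @describeIn estimate_impedance_scan One-row summary tibble.
#' @method glance qus_impedance
#' @export
glance.qus_impedance <- function(x, ...) {
  tibble(
    mean_mrayl = x$mean, sd_mrayl = x$sd, n_lines = x$n_lines,
    n_skipped = x$n_skipped,
    segmentation_thickness_mm = x$segmentation_thickness
  )
}

#' Impedance as a function of segmented tissue thickness
#'
#' Applies [sub_segment_by_thickness()] for each requested thickness and
#' estimates the impedance of each trimmed segmentation; outputs are aligned
#' to the input thicknesses.
#'
#' @inheritParams estimate_impedance_scan
#' @param thicknesses Positive, ascending thicknesses in mm.
#' @return A tibble of class `qus_impedance_sweep` with columns
#'   `thickness_mm`, `mean_mrayl`, `sd_mrayl`, `n_lines` and a list-column
#'   `estimate` of `qus_impedance` objects.
#' @export
impedance_vs_thickness <- function(segmented, cal, thicknesses,
                                   surface_window_mm = 0.2) {
  if (!(is.numeric(thicknesses) && length(thicknesses) >= 1 &&
        all(thicknesses > 0) && !is.unsorted(thicknesses, strictly = FALSE))) {
    abort("`thicknesses` must be positive and ascending.")
  }
  rows <- purrr::map(thicknesses, function(th) {
    est <- estimate_impedance_scan(
      sub_segment_by_thickness(segmented, th), cal,
      surface_window_mm = surface_window_mm
    )
    tibble(
      thickness_mm = th, mean_mrayl = est$mean, sd_mrayl = est$sd,
      n_lines = est$n_lines, estimate = list(est)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("qus_impedance_sweep", class(out))
  out
}
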