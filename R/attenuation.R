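#' Attenuation coefficient by the substitution method
#'
#' `alpha = -20 / (2 d) * log10(V_r / V_a)` in dB/mm: the round-trip amplitude
#' ratio of the reference-reflector echo beneath a tissue slab of thickness
#' `d` to the echo without tissue present. Positive when the tissue attenuates
#' (`V_r < V_a`). Vectorised over amplitude pairs.
#'
#' @param V_r Reference-reflector echo amplitude beneath tissue (> 0).
#' @param V_a Reference-reflector echo amplitude without tissue (> 0).
#' @param d Slab thickness in mm (> 0).
#' @return One-way attenuation coefficient in dB/mm.
#' @examples
#' estimate_attenuation(0.1, 1, 5) # 2 dB/mm
#' @export
estimate_attenuation <- function(V_r, V_a, d) {
  if (!is.numeric(V_r) || !is.numeric(V_a) || any(V_r <= 0) || any(V_a <= 0)) {
    abort("Echo amplitudes must be positive.")
  }
  assert_scalar_number(d, "d", positive = TRUE)
  -20 / (2 * d) * log10(V_r / V_a)
}

#' Attenuation from a simulated reference pair
#'
#' Convenience wrapper: extracts the peak envelope amplitudes of the
#' with-tissue and without-tissue quartz echoes and applies
#' [estimate_attenuation()] with the recorded slab thickness.
#'
#' @param pair A list with elements `with_tissue` and `without` as returned by
#'   [simulate_reference_pair()].
#' @param d Slab thickness in mm; defaults to the thickness recorded on the
#'   with-tissue echo.
#' @return Attenuation in dB/mm.
#' @export
attenuation_from_reference <- function(pair, d = NULL) {
  stopifnot(
    inherits(pair$with_tissue, "reference_echo"),
    inherits(pair$without, "reference_echo")
  )
  d <- d %||% pair$with_tissue$tissue_thickness
  estimate_attenuation(
    echo_amplitude(pair$with_tissue), echo_amplitude(pair$without), d
  )
}

#' Convert an attenuation coefficient from dB/mm to neper/mm
#'
#' `a' = alpha / 8.686`.
#'
#' @param alpha Attenuation in dB/mm (vectorised).
#' @return Attenuation in Np/mm.
#' @export
db_to_neper <- function(alpha) alpha / DB_PER_NEPER

#' Aggregate per-line attenuation values
#'
#' Bundles per-line attenuation estimates into an aggregate carrying both the
#' dB/mm and Np/mm scales (exactly consistent: `a' = alpha / 8.686` for every
#' stored pair) plus mean and standard deviation across lines.
#'
#' @param alpha_per_line Numeric vector of per-line attenuation values, dB/mm.
#' @param population_sd Population (n) rather than sample (n-1) standard
#'   deviation.
#' @return A `qus_attenuation` object.
#' @export
attenuation_estimate <- function(alpha_per_line, population_sd = TRUE) {
  if (!is.numeric(alpha_per_line) || length(alpha_per_line) < 1) {
    abort("`alpha_per_line` must be a non-empty numeric vector.")
  }
  structure(
    list(
      per_line = tibble(
        line = seq_along(alpha_per_line),
        alpha_db_mm = alpha_per_line,
        a_prime_np_mm = db_to_neper(alpha_per_line)
      ),
      mean = mean(alpha_per_line),
      sd = agg_sd(alpha_per_line, population_sd),
      mean_np_mm = db_to_neper(mean(alpha_per_line))
    ),
    class = "qus_attenuation"
  )
}

#' @export
print.qus_attenuation <- function(x, ...) {
  cat(sprintf(
    "<qus_attenuation> alpha = %.3f +/- %.3f dB/mm (a' = %.4f Np/mm), %d line(s)\n",
    x$mean, x$sd, x$mean_np_mm, nrow(x$per_line)
  ))
  invisible(x)
}

#' @describeIn attenuation_estimate Per-line tibble with both scales.
#' @param x A `qus_attenuation`.
#' @param ... Unused.
#' @method tidy qus_attenuation
#' @export
tidy.qus_attenuation <- function(x, ...) x$per_line

#' @describeIn attenuation_estimate One-row summary tibble.
#' @method glance qus_attenuation
#' @export
glance.qus_attenuation <- function(x, ...) {
  tibble(
    mean_db_mm = x$mean, sd_db_mm = x$sd, mean_np_mm = x$mean_np_mm,
    n_lines = nrow(x$per_line)
  )
}
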