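#' Gaussian-enveloped acoustic pulse
#'
#' Constructs the transmit pulse used throughout the simulator: a sinusoid at
#' `center_frequency` under a Gaussian envelope whose -6 dB spectral full width
#' divided by the center frequency equals `fractional_bandwidth`. The envelope
#' peaks at the pulse center (time zero).
#'
#' @param center_frequency Center frequency in Hz (48e6 for the imaging
#'   context, 4e6 for the therapy context).
#' @param fractional_bandwidth -6 dB fractional bandwidth (dimensionless),
#'   default 0.5.
#' @param sampling_rate Sampling rate in Hz; must be at least four times the
#'   center frequency.
#' @param amplitude Peak amplitude in arbitrary linear units.
#' @param n_sigma Half-duration of the recorded pulse in units of the envelope
#'   standard deviation; the default (4) truncates the Gaussian below 1e-3 of
#'   its peak.
#'
#' @return An object of class `acoustic_pulse`: a list with `waveform`, `t`
#'   (seconds, centered on 0), and the construction parameters.
#' @examples
#' p <- acoustic_pulse(48e6, 0.5, 400e6)
#' plot(p$t * 1e9, p$waveform, type = "l", xlab = "ns", ylab = "amplitude")
#' @export
acoustic_pulse <- function(center_frequency = 48e6, fractional_bandwidth = 0.5,
                           sampling_rate = 400e6, amplitude = 1, n_sigma = 4) {
  assert_scalar_number(center_frequency, "center_frequency", positive = TRUE)
  assert_scalar_number(fractional_bandwidth, "fractional_bandwidth", positive = TRUE)
  assert_scalar_number(sampling_rate, "sampling_rate", positive = TRUE)
  assert_scalar_number(amplitude, "amplitude", positive = TRUE)
  if (sampling_rate < 4 * center_frequency) {
    abort(sprintf(
      paste0(
        "Nyquist violation: sampling_rate (%.3g Hz) must be at least 4x the ",
        "center frequency (%.3g Hz) to represent the pulse faithfully."
      ),
      sampling_rate, center_frequency
    ))
  }
  # A Gaussian envelope exp(-t^2 / (2 sigma_t^2)) has an amplitude spectrum
  # with -6 dB (half-amplitude) full width 2 * sigma_f * sqrt(2 ln 2) where
  # sigma_f = 1 / (2 pi sigma_t).
  sigma_t <- sqrt(2 * log(2)) / (pi * fractional_bandwidth * center_frequency)
  half_n <- ceiling(n_sigma * sigma_t * sampling_rate)
  t <- seq(-half_n, half_n) / sampling_rate
  waveform <- amplitude * exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * center_frequency * t)
  structure(
    list(
      waveform = waveform,
      t = t,
      center_frequency = center_frequency,
      fractional_bandwidth = fractional_bandwidth,
      sampling_rate = sampling_rate,
      amplitude = amplitude,
      duration = 2 * half_n / sampling_rate,
      sigma_t = sigma_t
    ),
    class = "acoustic_pulse"
  )
}

#' @export
print.acoustic_pulse <- function(x, ...) {
  cat(sprintf(
    "<acoustic_pulse> %.3g MHz, %.0f%% bandwidth, fs = %.3g MHz, %d samples\n",
    x$center_frequency / 1e6, 100 * x$fractional_bandwidth,
    x$sampling_rate / 1e6, length(x$waveform)
  ))
  invisible(x)
}
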