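# shared numerical helpers

# Analytic signal of a real vector via the frequency-domain construction:
# zero the negative frequencies, double the positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 1L) {
    return(complex(real = x, imaginary = 0))
  }
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Envelope (instantaneous amplitude) of a real RF vector.
envelope_mag <- function(x) Mod(analytic_signal(x))

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

# dB <-> neper conversion constant for amplitude coefficients
DB_PER_NEPER <- 8.686

# depth (mm) of 1-based sample index under an assumed sound speed
sample_depth_mm <- function(index, sampling_rate, sound_speed, depth_origin = 0) {
  depth_origin + (index - 1) * sound_speed / (2 * sampling_rate) * 1e3
}
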