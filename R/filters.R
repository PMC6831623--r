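# Zero-phase Butterworth-magnitude filtering and coloured-noise generators.
#
# Filtering is done in the frequency domain: the gain applied is the
# squared magnitude of an analog Butterworth band-pass, i.e. exactly the
# net response of a forward-backward (filtfilt) pass, with odd-reflection
# padding to suppress edge transients. This keeps the filter zero-phase by
# construction and lets tests evaluate the designed response in closed form.

#' Frequency response of the zero-phase band-pass
#'
#' Net amplitude gain (forward-backward equivalent, i.e. |H|^2 of the
#' analog Butterworth prototype) at frequencies `f`.
#'
#' @param f frequencies in Hz
#' @param lo_hz,hi_hz band edges in Hz
#' @param order Butterworth prototype order (default 8; at the default the
#'   response is at least 20 dB down at 0.2 Hz and at 60 Hz for a 1-50 Hz
#'   band)
#' @return gain (amplitude ratio) at each frequency
#' @export
bandpass_response <- function(f, lo_hz = 1, hi_hz = 50, order = 8) {
  w <- ifelse(f == 0, Inf, (f^2 - lo_hz * hi_hz) / (f * (hi_hz - lo_hz)))
  ifelse(is.infinite(w), 0, 1 / (1 + w^(2 * order)))
}

fft_apply_gain <- function(x, gain_fun, fs, pad_s = 2) {
  n <- length(x)
  np <- min(n - 1, max(1, round(pad_s * fs)))
  # odd reflection about the end points
  pre <- 2 * x[1] - x[seq(np + 1, 2)]
  post <- 2 * x[n] - x[seq(n - 1, n - np)]
  xe <- c(pre, x, post)
  ne <- length(xe)
  f <- (seq_len(ne) - 1) / ne * fs
  f <- ifelse(f > fs / 2, fs - f, f)      # two-sided axis folded
  X <- stats::fft(xe) * gain_fun(f)
  y <- Re(stats::fft(X, inverse = TRUE)) / ne
  y[seq(np + 1, np + n)]
}

#' Zero-phase band-pass filter a recording or signal matrix
#'
#' @param x an `eeg_recording`, or a channels x samples matrix/vector
#' @param lo_hz,hi_hz pass-band edges in Hz (defaults 1 and 50)
#' @param order Butterworth prototype order
#' @param fs sampling rate, required when `x` is a bare matrix/vector
#' @return object of the same kind as `x`, filtered, same length
#' @export
bandpass <- function(x, lo_hz = 1, hi_hz = 50, order = 8, fs = NULL) {
  if (inherits(x, "eeg_recording")) {
    x$data <- bandpass(x$data, lo_hz, hi_hz, order, fs = x$fs)
    return(x)
  }
  if (is.null(fs)) stopf("fs is required for matrix input")
  if (!(lo_hz > 0 && lo_hz < hi_hz)) stopf("need 0 < lo_hz < hi_hz")
  if (hi_hz >= fs / 2)
    stopf("hi_hz (%g) must be below the Nyquist frequency (%g)", hi_hz, fs / 2)
  g <- function(f) bandpass_response(f, lo_hz, hi_hz, order)
  if (is.matrix(x)) {
    t(apply(x, 1, fft_apply_gain, gain_fun = g, fs = fs))
  } else {
    fft_apply_gain(x, g, fs)
  }
}

#' Coloured-noise generators used by the synthetic sources
#'
#' `pink_noise` draws unit-variance 1/f^beta noise; `bandlimited_noise`
#' draws unit-variance Gaussian noise band-passed to `[lo, hi]` Hz.
#'
#' @param n number of samples
#' @param fs sampling rate in Hz
#' @param beta spectral exponent
#' @export
pink_noise <- function(n, fs, beta = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) / n * fs
  f <- ifelse(f > fs / 2, fs - f, f)
  shape <- ifelse(f <= 0, 0, f^(-beta / 2))
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' @rdname pink_noise
#' @param lo,hi band edges in Hz
#' @param order Butterworth prototype order of the shaping filter
#' @export
bandlimited_noise <- function(n, fs, lo, hi, order = 8) {
  x <- stats::rnorm(n)
  y <- fft_apply_gain(x, function(f) bandpass_response(f, lo, hi, order), fs)
  s <- stats::sd(y)
  if (s < .Machine$double.eps) return(y)
  y / s
}

# positive (log-normal) amplitude envelopes for the source oscillations.
#
# burst_envelope: second-scale burstiness — the positive excess kurtosis
# real band oscillations show and that ICA needs to separate
# otherwise-Gaussian sources. Depth is mild so that genuine bursts stay
# below the 5-SD ASR threshold (real sessions lose only ~1% to ASR).
#
# slow_envelope: minute-scale power drift (period ~20 s and slower), the
# dominant across-trial band-power variability of resting oscillations.
# It is the nuisance component that per-trial rest-baseline normalization
# is designed to cancel, and it sets the natural scale of the calibrated
# standardized emotion effects.
burst_envelope <- function(n, fs, rate_hz = 2, depth = 0.25) {
  lognormal_envelope(n, fs, rate_hz, depth)
}

slow_envelope <- function(n, fs, rate_hz = 0.02, depth = 0.5) {
  lognormal_envelope(n, fs, rate_hz, depth)
}

lognormal_envelope <- function(n, fs, rate_hz, depth) {
  slow <- fft_apply_gain(stats::rnorm(n),
                         function(f) as.numeric(f <= rate_hz), fs)
  s <- stats::sd(slow)
  if (s < .Machine$double.eps) return(rep(1, n))
  # theoretical log-normal normalization (E[e^2] = 1): an empirical
  # per-draw normalization would cancel the very across-draw level
  # variance the slow envelope exists to provide
  exp(depth * slow / s - depth^2)
}
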