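# Spectro-temporal band power of component activations: 2-s 50%-overlap
# Hamming STFT in dB, grouping into the five canonical bands, and per-trial
# z-normalization against the trial's own preceding 30-s rest.

#' Canonical EEG frequency bands (Hz, inclusive edges)
#' @export
eeg_bands <- function() {
  list(delta = c(1, 3), theta = c(4, 7), alpha = c(8, 13),
       beta = c(14, 30), gamma = c(31, 50))
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

#' Short-time Fourier log power
#'
#' Hamming-windowed frames with hop = window/2 (50% overlap) by default.
#' Power is one-sided PSD in dB (10 log10); frequency resolution is
#' `1/window_s` Hz. Frames are those that fit fully inside the signal.
#'
#' @param x activation time series
#' @param fs sampling rate in Hz
#' @param window_s window length in seconds (default 2)
#' @param overlap fractional overlap (default 0.5)
#' @return list with `power` (freq x frames, dB), `freq` (Hz), `time`
#'   (frame start, s)
#' @export
stft_logpower <- function(x, fs, window_s = 2, overlap = 0.5) {
  win <- round(window_s * fs)
  if (length(x) < win)
    stopf("signal (%d samples) shorter than one %g-s window", length(x),
          window_s)
  hop <- max(1, round(win * (1 - overlap)))
  nfrm <- (length(x) - win) %/% hop + 1
  w <- hamming_window(win)
  u <- sum(w^2) * fs                      # PSD normalization
  nf <- win %/% 2 + 1
  P <- matrix(0, nf, nfrm)
  for (k in seq_len(nfrm)) {
    seg <- x[((k - 1) * hop + 1):((k - 1) * hop + win)] * w
    sp <- Mod(stats::fft(seg)[1:nf])^2 / u
    sp[2:(nf - 1)] <- 2 * sp[2:(nf - 1)]  # one-sided
    P[, k] <- sp
  }
  list(power = 10 * log10(pmax(P, 1e-300)),
       freq = (seq_len(nf) - 1) / window_s,
       time = (seq_len(nfrm) - 1) * hop / fs)
}

#' Group a time-frequency matrix into band log-power series
#'
#' Per frame, the band value is the mean of the dB bins whose centre
#' frequency lies inside the band (edges inclusive).
#'
#' @param tf result of [stft_logpower()]
#' @param bands named list of `c(lo, hi)` (default [eeg_bands()])
#' @return frames x bands matrix of dB values
#' @export
band_series <- function(tf, bands = eeg_bands()) {
  out <- sapply(bands, function(b) {
    sel <- which(tf$freq >= b[1] & tf$freq <= b[2])
    if (length(sel) == 0)
      stopf("band [%g, %g] Hz outside the frequency axis", b[1], b[2])
    colMeans(tf$power[sel, , drop = FALSE])
  })
  matrix(out, ncol = length(bands), dimnames = list(NULL, names(bands)))
}

#' Baseline-normalize one trial's band series against its rest
#'
#' z(t) = (x(t) - mu_rest) / sd_rest, with the mean and SD taken over the
#' frames of the trial's own preceding rest period (in dB units).
#'
#' @param stim_series stimulus-period values (dB), one band
#' @param rest_series rest-period values (dB), same band, >= 2 frames
#' @param eps degenerate-baseline guard on sd_rest (dB)
#' @return list with `z`, `trial_mean`, `mu_rest`, `sigma_rest`
#' @export
baseline_normalize <- function(stim_series, rest_series, eps = 1e-6) {
  if (length(rest_series) < 2) stopf("rest series needs >= 2 frames")
  mu <- mean(rest_series)
  sg <- stats::sd(rest_series)
  if (!is.finite(sg) || sg <= eps)
    stopf("degenerate baseline: rest SD = %g dB", sg)
  z <- (stim_series - mu) / sg
  list(z = z, trial_mean = mean(z), mu_rest = mu, sigma_rest = sg)
}

#' Per-trial normalized band power of an activation
#'
#' Runs the STFT separately on each trial's rest and stimulus segments
#' (frames fully inside each segment), groups into bands, and z-normalizes
#' the stimulus series against the trial's rest. Trials with a degenerate
#' rest baseline are flagged and carry NA values.
#'
#' @param activation component activation (same sample grid as the events)
#' @param events trial table (columns rest_onset, stim_onset, stim_end;
#'   1-based sample indices)
#' @param fs sampling rate
#' @param window_s,overlap STFT parameters
#' @return list with `trial_means` (trials x bands), `series` (list per
#'   trial of frames x bands z-matrices), `flagged` (logical per trial)
#' @export
trial_band_power <- function(activation, events, fs, window_s = 2,
                             overlap = 0.5) {
  bands <- eeg_bands()
  nt <- nrow(events)
  tm <- matrix(NA_real_, nt, length(bands),
               dimnames = list(NULL, names(bands)))
  series <- vector("list", nt)
  flagged <- logical(nt)
  for (tr in seq_len(nt)) {
    rest <- activation[events$rest_onset[tr]:(events$stim_onset[tr] - 1)]
    stim <- activation[events$stim_onset[tr]:events$stim_end[tr]]
    bs_rest <- band_series(stft_logpower(rest, fs, window_s, overlap), bands)
    bs_stim <- band_series(stft_logpower(stim, fs, window_s, overlap), bands)
    z <- matrix(NA_real_, nrow(bs_stim), length(bands),
                dimnames = list(NULL, names(bands)))
    ok <- TRUE
    for (b in names(bands)) {
      res <- tryCatch(baseline_normalize(bs_stim[, b], bs_rest[, b]),
                      error = function(e) NULL)
      if (is.null(res)) { ok <- FALSE; break }
      z[, b] <- res$z
      tm[tr, b] <- res$trial_mean
    }
    if (!ok) {
      flagged[tr] <- TRUE
      tm[tr, ] <- NA_real_
      z[] <- NA_real_
    }
    series[[tr]] <- z
  }
  list(trial_means = tm, series = series, flagged = flagged)
}

#' Welch power spectral density in 1-Hz bins
#'
#' 1-s Hamming segments with 50% overlap averaged into a periodogram,
#' reported as log10 power in 1-Hz bins over `range` (used as the spectral
#' block of clustering features).
#'
#' @param x time series
#' @param fs sampling rate
#' @param range `c(lo, hi)` Hz, inclusive integer bins
#' @return named numeric vector of log10 power per 1-Hz bin
#' @export
welch_logpsd <- function(x, fs, range = c(1, 50)) {
  tf <- stft_logpower(x, fs, window_s = 1, overlap = 0.5)
  # average in linear power, then log
  lin <- rowMeans(10^(tf$power / 10))
  sel <- which(tf$freq >= range[1] & tf$freq <= range[2] &
                 abs(tf$freq - round(tf$freq)) < 1e-9)
  out <- log10(pmax(lin[sel], 1e-300))
  names(out) <- paste0(tf$freq[sel], "Hz")
  out
}

#' Export per-trial band-power tables in long format
#'
#' @param bp result of [trial_band_power()]
#' @param meta named list (subject, session, cluster/component id) prefixed
#'   to every row
#' @param path optional TSV output path
#' @return long-format data.frame (one row per trial x band)
#' @export
band_power_table <- function(bp, meta = list(), path = NULL) {
  nt <- nrow(bp$trial_means)
  bands <- colnames(bp$trial_means)
  df <- data.frame(trial = rep(seq_len(nt), each = length(bands)),
                   band = rep(bands, nt),
                   z_mean = as.vector(t(bp$trial_means)),
                   flagged = rep(bp$flagged, each = length(bands)))
  for (nm in rev(names(meta))) df <- cbind(stats::setNames(
    data.frame(rep(meta[[nm]], nrow(df))), nm), df)
  if (!is.null(path))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
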