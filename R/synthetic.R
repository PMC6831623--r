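# Synthetic multiday EEG with known ground truth.
#
# The generator emulates the acquisition protocol of a multi-session
# music-listening study: 30-channel scalp EEG, 8 sessions per subject,
# 24 trials per session of 30-s rest followed by 60-s stimulus, dipolar
# cortical sources with band-limited bursty oscillations over a 1/f
# background, day-to-day source presence/absence, blink and EMG artifacts,
# sensor noise, and 5-point valence/arousal self-reports. Everything is a
# pure function of the scenario (including its seed).

#' Specify a simulated cortical source
#'
#' @param location 3-vector, head-frame mm, strictly inside the brain sphere
#' @param orientation moment direction (normalized internally)
#' @param peaks list of oscillatory peaks, each
#'   `list(band = "alpha", centre = 10, amplitude = 6)`; `amplitude` is the
#'   oscillation SD in source units (uV)
#' @param background_exponent spectral exponent of the 1/f background
#' @param background_sd background SD in source units (projected columns are
#'   unit-RMS across channels, so this is roughly the mean channel SD in uV
#'   contributed by the source); 0 gives a pure oscillation
#' @param effect optional emotion modulation:
#'   `list(dimension = "valence", band = "beta", d = 1)` with `d` the signed
#'   standardized effect size (units of across-trial SD of trial-mean log
#'   band power) applied during stimulus windows
#' @param presence_prob per-session Bernoulli probability that the source is
#'   active at all
#' @param label optional name
#' @export
source_spec <- function(location, orientation = c(0, 0, 1),
                        peaks = list(), background_exponent = 1,
                        background_sd = 4, effect = NULL,
                        presence_prob = 1, label = NULL) {
  if (!is.null(effect)) {
    stopifnot(effect$dimension %in% c("valence", "arousal"),
              effect$band %in% names(eeg_bands()))
    if (!any(vapply(peaks, function(p) p$band, "") == effect$band))
      stopf("effect band '%s' has no matching oscillatory peak", effect$band)
  }
  if (presence_prob < 0 || presence_prob > 1)
    stopf("presence_prob must be in [0, 1]")
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(location = as.numeric(location), orientation = orientation,
                 peaks = peaks, background_exponent = background_exponent,
                 background_sd = background_sd, effect = effect,
                 presence_prob = presence_prob,
                 label = label %||% "source"),
            class = "eeg_source_spec")
}

#' Default source set emulating commonly reported cortical clusters
#'
#' Nine dipolar sources in frontal (left/central/right), central midline,
#' sensorimotor (left/right), superior parietal and occipital (left/right)
#' regions. Frontal/midline sources carry a theta peak, posterior and
#' sensorimotor sources an alpha peak (sensorimotor/parietal with a minor
#' beta peak). Two sources are emotion-modulated by default: central
#' midline beta by valence and superior parietal beta by arousal (positive
#' state = higher power, i.e. suppression with the negative/low state).
#'
#' @param effect_d standardized effect size for the two modulated sources
#' @export
default_sources <- function(effect_d = 1.0) {
  th <- function(a = 5.2) list(list(band = "theta", centre = 6, amplitude = a))
  al <- function(a = 6.4) list(list(band = "alpha", centre = 10, amplitude = a))
  albe <- function() list(list(band = "alpha", centre = 10, amplitude = 6),
                          list(band = "beta", centre = 20, amplitude = 3.6))
  list(
    source_spec(c(55, 0, 35), c(1, 0, 0.4), th(), presence_prob = 1,
                label = "frontal_central"),
    source_spec(c(10, 0, 70), c(0, 0, 1),
                c(th(4.4), list(list(band = "beta", centre = 22,
                                     amplitude = 3.2))),
                presence_prob = 1,
                effect = list(dimension = "valence", band = "beta",
                              d = effect_d),
                label = "central_midline"),
    source_spec(c(45, 35, 30), c(0.6, 0.8, 0), th(4.4),
                presence_prob = 0.8, label = "frontal_left"),
    source_spec(c(45, -35, 30), c(0.6, -0.8, 0), th(4.4),
                presence_prob = 0.8, label = "frontal_right"),
    source_spec(c(0, 45, 55), c(0, 0.7, 0.7), albe(),
                presence_prob = 0.9, label = "sensorimotor_left"),
    source_spec(c(0, -45, 55), c(0, -0.7, 0.7), albe(),
                presence_prob = 0.9, label = "sensorimotor_right"),
    source_spec(c(-35, 0, 60), c(-0.4, 0, 0.9),
                c(al(5.6), list(list(band = "beta", centre = 18,
                                     amplitude = 3.2))),
                presence_prob = 0.85,
                effect = list(dimension = "arousal", band = "beta",
                              d = effect_d),
                label = "superior_parietal"),
    source_spec(c(-60, 25, 25), c(-0.9, 0.3, 0.2), al(7.2),
                presence_prob = 0.75, label = "occipital_left"),
    source_spec(c(-60, -25, 25), c(-0.9, -0.3, 0.2), al(7.2),
                presence_prob = 0.75, label = "occipital_right")
  )
}

#' Default per-pole rating distribution
#'
#' Categorical distributions over ratings 1..5 for the intended positive and
#' negative pole of a dimension; sharply peaked on \{4,5\} (or \{1,2\}) with
#' P(match) = 0.8 so that dichotomization at 3 is imperfect, as with real
#' self-reports.
#' @export
default_rating_model <- function() {
  pos <- c(0.02, 0.05, 0.13, 0.40, 0.40)
  list(positive = pos, negative = rev(pos))
}

#' Specify a simulation scenario
#'
#' Defaults follow the emulated protocol: 8 sessions of 24 trials
#' (30-s rest + 60-s stimulus) for 10 subjects, 30-channel montage.
#' The sampling default is 250 Hz for desk-scale speed; set `fs = 500` for
#' the full acquisition rate. Emotion effect sizes are calibrated here,
#' once, by bisection (see [calibrate_effect()]).
#'
#' @param n_subjects,n_sessions,n_trials counts; `n_trials` must be
#'   divisible by 4 (one trial per emotion quadrant per block of four)
#' @param fs sampling rate in Hz
#' @param rest_s,stim_s rest and stimulus durations in seconds
#' @param sources list of [source_spec()] objects
#' @param artifact_rates `c(blinks_per_min =, emg_per_min =)`
#' @param sensor_noise_sd white sensor noise SD in uV
#' @param rating_model see [default_rating_model()]
#' @param location_jitter_mm SD of per-session dipole location jitter
#' @param hm head model; `montage` defaults to the standard 30-channel set
#' @param montage electrode montage
#' @param seed integer seed; the entire study is a pure function of the
#'   scenario including this seed
#' @export
scenario_spec <- function(n_subjects = 10, n_sessions = 8, n_trials = 24,
                          fs = 250, rest_s = 30, stim_s = 60,
                          sources = default_sources(),
                          artifact_rates = c(blinks_per_min = 6,
                                             emg_per_min = 4),
                          sensor_noise_sd = 2,
                          rating_model = default_rating_model(),
                          location_jitter_mm = 2,
                          hm = head_model(),
                          montage = standard_montage_30(hm),
                          seed = 1L) {
  if (n_trials %% 4 != 0) stopf("n_trials must be divisible by 4")
  if (rest_s <= 0 || stim_s <= 0) stopf("rest_s and stim_s must be > 0")
  for (pole in rating_model)
    if (abs(sum(pole) - 1) > 1e-8) stopf("rating distributions must sum to 1")
  br <- brain_radius(hm)
  for (s in sources) {
    if (sqrt(sum(s$location^2)) >= br)
      stopf("source '%s' is not inside the brain sphere", s$label)
    for (p in s$peaks)
      if (p$centre <= 0 || p$centre >= fs / 2)
        stopf("peak centre %g Hz outside (0, fs/2)", p$centre)
  }
  sc <- structure(list(n_subjects = as.integer(n_subjects),
                       n_sessions = as.integer(n_sessions),
                       n_trials = as.integer(n_trials),
                       fs = fs, rest_s = rest_s, stim_s = stim_s,
                       sources = sources, artifact_rates = artifact_rates,
                       sensor_noise_sd = sensor_noise_sd,
                       rating_model = rating_model,
                       location_jitter_mm = location_jitter_mm,
                       hm = hm, montage = montage, seed = as.integer(seed)),
                  class = "eeg_scenario")
  # one-off effect-size calibration per modulated source
  for (i in seq_along(sc$sources)) {
    ef <- sc$sources[[i]]$effect
    if (!is.null(ef) && ef$d != 0)
      sc$sources[[i]]$effect$multiplier <- calibrate_effect(sc$sources[[i]], sc)
  }
  sc
}

#' @export
print.eeg_scenario <- function(x, ...) {
  cat(sprintf(paste0("<eeg_scenario> %d subjects x %d sessions x %d trials ",
                     "(%gs rest + %gs stim) @ %g Hz, %d sources, seed %d\n"),
              x$n_subjects, x$n_sessions, x$n_trials, x$rest_s, x$stim_s,
              x$fs, length(x$sources), x$seed))
  invisible(x)
}

#' Calibrate an emotion effect to a standardized size
#'
#' Finds the peak-power multiplier `m` such that scaling the source's
#' effect-band oscillation variance by `m` for positive-state trials and by
#' `1/m` for negative-state trials yields a realized standardized
#' difference of trial-mean log band power of approximately `|d|`
#' (difference divided by the across-trial SD of the unmodulated trial-mean
#' log band power). Uses common random numbers over a fixed internal seed
#' and bisection on log(m); the result depends only on the source and the
#' protocol timing, never on the scenario seed.
#'
#' @param src a [source_spec()] with a non-null effect
#' @param sc the scenario (for fs and stimulus duration)
#' @return the power multiplier `m` (> 1 for d > 0, < 1 for d < 0)
#' @export
calibrate_effect <- function(src, sc) {
  ef <- src$effect
  band <- eeg_bands()[[ef$band]]
  fs <- sc$fs; len <- round(sc$stim_s * fs)
  n_cal <- 48
  win <- round(2 * fs); hop <- win %/% 2
  nfrm <- max(1, (len - win) %/% hop + 1)
  hamm <- hamming_window(win)
  freqs <- (0:(win %/% 2)) / 2   # 2-s window -> 0.5 Hz resolution
  bsel <- which(freqs >= band[1] & freqs <= band[2])
  # per-trial quadratic pieces of band power in the multiplier a:
  # |B + a P|^2 = |B|^2 + 2a Re(B conj(P)) + a^2 |P|^2
  stats_tr <- with_seed(derive_seed(760117L, "effect-calib", src$label), {
    lapply(seq_len(n_cal), function(i) {
      bg <- pink_noise(len, fs, src$background_exponent) * src$background_sd
      pk <- numeric(len)
      # the minute-scale power drift is slower than one surrogate trial:
      # each calibration trial samples the slow log-normal level once
      slow_gain <- exp(0.5 * stats::rnorm(1) - 0.25)
      for (p in src$peaks) {
        b <- eeg_bands()[[p$band]]
        o <- bandlimited_noise(len, fs, b[1], b[2]) *
          burst_envelope(len, fs) * slow_gain * p$amplitude
        if (p$band == ef$band) pk <- pk + o else bg <- bg + o
      }
      B2 <- BP <- P2 <- 0
      for (k in seq_len(nfrm)) {
        idx <- ((k - 1) * hop + 1):((k - 1) * hop + win)
        FB <- stats::fft(bg[idx] * hamm)[bsel]
        FP <- stats::fft(pk[idx] * hamm)[bsel]
        B2 <- B2 + mean(Mod(FB)^2); BP <- BP + mean(Re(FB * Conj(FP)))
        P2 <- P2 + mean(Mod(FP)^2)
      }
      c(B2, BP, P2) / nfrm
    })
  })
  trial_logbp <- function(a) vapply(stats_tr, function(s)
    log10(max(s[1] + 2 * a * s[2] + a^2 * s[3], 1e-300)), numeric(1))
  base <- trial_logbp(1)
  sd0 <- stats::sd(base)
  target <- abs(ef$d) * sd0
  gap <- function(logm) {
    m <- exp(logm)
    mean(trial_logbp(sqrt(m))) - mean(trial_logbp(sqrt(1 / m))) - target
  }
  lo <- 0; hi <- log(10)
  while (gap(hi) < 0 && hi < log(1e6)) hi <- hi * 2
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (gap(mid) < 0) lo <- mid else hi <- mid
  }
  m <- exp((lo + hi) / 2)
  if (ef$d < 0) m <- 1 / m
  m
}

#' Which sources are active in a given session
#'
#' Per-session Bernoulli presence draws, a pure function of
#' (scenario seed, subject, session).
#'
#' @param sc scenario
#' @param subject_id,session_id indices
#' @return integer indices into `sc$sources`
#' @export
session_active_sources <- function(sc, subject_id, session_id) {
  with_seed(derive_seed(sc$seed, "presence", subject_id, session_id), {
    p <- vapply(sc$sources, `[[`, numeric(1), "presence_prob")
    which(stats::runif(length(p)) < p)
  })
}

# trial quadrant schedule: blocks of four, one trial per quadrant per block,
# order shuffled within block
quadrant_schedule <- function(n_trials) {
  quads <- data.frame(valence = c("positive", "positive", "negative",
                                  "negative"),
                      arousal = c("high", "low", "high", "low"))
  idx <- unlist(lapply(seq_len(n_trials / 4), function(b) sample.int(4)))
  quads[idx, , drop = FALSE]
}

draw_rating <- function(pole, model) {
  probs <- if (pole %in% c("positive", "high")) model$positive else
    model$negative
  sample.int(5, 1, prob = probs)
}

blink_template <- function(fs) {
  t <- seq(0, 0.4, by = 1 / fs)
  sin(2 * pi * t / 0.4) * exp(-((t - 0.2) / 0.12)^2)
}

frontal_column <- function(m, hm) {
  front <- c(sin(72 * pi / 180), 0, cos(72 * pi / 180)) * scalp_radius(hm)
  d2 <- rowSums(sweep(m$positions, 2, front)^2)
  w <- exp(-d2 / (2 * 35^2))
  w / max(w)
}

temporal_channels <- function(m) {
  cand <- which(m$labels %in% c("T7", "T8", "FT7", "FT8", "TP7", "TP8"))
  if (length(cand) == 0) cand <- seq_along(m$labels)
  cand
}

#' Simulate one recording session
#'
#' Deterministic given (scenario seed, subject_id, session_id). The data are
#' the sum over active sources of (unit-RMS scalp projection x source
#' activation), plus blink/EMG artifacts and white sensor noise. Per-trial
#' emotion effects are applied as multiplicative band-power changes of the
#' calibrated size during the stimulus window.
#'
#' @param sc scenario from [scenario_spec()]
#' @param subject_id,session_id 1-based indices
#' @return `list(recording = <eeg_recording>, truth = <ground truth>)`;
#'   the truth holds active-source indices, mixing columns, and per-trial
#'   per-source band-power multipliers
#' @export
simulate_session <- function(sc, subject_id = 1, session_id = 1) {
  active <- session_active_sources(sc, subject_id, session_id)
  if (length(active) == 0 && sc$sensor_noise_sd <= 0)
    stopf("degenerate scenario: no active sources and zero sensor noise")
  fs <- sc$fs
  nrest <- round(sc$rest_s * fs); nstim <- round(sc$stim_s * fs)
  seg <- nrest + nstim
  n <- sc$n_trials * seg
  nc <- n_channels(sc$montage)
  with_seed(derive_seed(sc$seed, "session", subject_id, session_id), {
    quads <- quadrant_schedule(sc$n_trials)
    valence <- vapply(quads$valence, draw_rating, 1L, model = sc$rating_model)
    arousal <- vapply(quads$arousal, draw_rating, 1L, model = sc$rating_model)
    data <- matrix(stats::rnorm(nc * n, sd = sc$sensor_noise_sd), nc, n)
    mixing <- matrix(0, nc, length(active))
    bp_mult <- matrix(1, sc$n_trials, length(active))
    for (j in seq_along(active)) {
      src <- sc$sources[[active[j]]]
      loc <- src$location
      if (sc$location_jitter_mm > 0) {
        repeat {
          cand <- loc + stats::rnorm(3, sd = sc$location_jitter_mm)
          if (sqrt(sum(cand^2)) < brain_radius(sc$hm) - 1) { loc <- cand; break }
        }
      }
      g <- lead_field(loc, src$orientation, sc$montage, sc$hm)
      col <- g / sqrt(mean(g^2))
      mixing[, j] <- col
      ef <- src$effect
      # waveforms are continuous across the whole session (no trial-boundary
      # discontinuities); noise-driven oscillations have random phase in
      # every trial by construction
      act <- pink_noise(n, fs, src$background_exponent) * src$background_sd
      for (p in src$peaks) {
        osc_band <- eeg_bands()[[p$band]]
        osc <- bandlimited_noise(n, fs, osc_band[1], osc_band[2]) *
          burst_envelope(n, fs) * slow_envelope(n, fs) * p$amplitude
        if (!is.null(ef) && !is.null(ef$multiplier) && p$band == ef$band) {
          # per-trial stimulus-window amplitude gain with smooth 0.2-s ramps
          gain <- rep(1, n)
          ramp <- max(2L, round(0.2 * fs))
          for (tr in seq_len(sc$n_trials)) {
            pole <- if (ef$dimension == "valence") quads$valence[tr] else
              quads$arousal[tr]
            a <- if (pole %in% c("positive", "high"))
              sqrt(ef$multiplier) else sqrt(1 / ef$multiplier)
            s0 <- (tr - 1) * seg + nrest + 1
            s1 <- tr * seg
            gain[s0:s1] <- a
            up <- s0:min(s0 + ramp - 1, s1)
            gain[up] <- 1 + (a - 1) *
              (1 - cos(pi * seq_along(up) / length(up))) / 2
            if (s1 < n) {
              dn <- s1:min(s1 + ramp - 1, n)
              gain[dn] <- a + (1 - a) *
                (1 - cos(pi * seq_along(dn) / length(dn))) / 2
            }
            bp_mult[tr, j] <- a^2
          }
          osc <- osc * gain
        }
        act <- act + osc
      }
      data <- data + col %o% act
    }
    # blink artifacts: Poisson arrivals, stereotyped biphasic template on a
    # frontal-dominant column
    blink_col <- frontal_column(sc$montage, sc$hm)
    tmpl <- blink_template(fs)
    nb <- stats::rpois(1, sc$artifact_rates[["blinks_per_min"]] * n / fs / 60)
    if (nb > 0) {
      for (t0 in sort(stats::runif(nb, 1, n - length(tmpl)))) {
        idx <- floor(t0) + seq_along(tmpl) - 1
        amp <- stats::rnorm(1, 120, 20)
        data[, idx] <- data[, idx] + amp * (blink_col %o% tmpl)
      }
    }
    # EMG bursts: 20-50 Hz noise of 0.5-2 s on random temporal channels
    ne <- stats::rpois(1, sc$artifact_rates[["emg_per_min"]] * n / fs / 60)
    tch <- temporal_channels(sc$montage)
    if (ne > 0) {
      for (k in seq_len(ne)) {
        dur <- round(stats::runif(1, 0.5, 2) * fs)
        t0 <- floor(stats::runif(1, 1, n - dur))
        ch <- sample(tch, 1)
        env <- sin(pi * seq_len(dur) / dur)
        burst <- bandlimited_noise(dur, fs, 20, min(50, fs / 2 - 1)) * env * 20
        data[ch, t0:(t0 + dur - 1)] <- data[ch, t0:(t0 + dur - 1)] + burst
      }
    }
    events <- data.frame(
      trial = seq_len(sc$n_trials),
      rest_onset = (seq_len(sc$n_trials) - 1) * seg + 1,
      stim_onset = (seq_len(sc$n_trials) - 1) * seg + nrest + 1,
      stim_end = seq_len(sc$n_trials) * seg,
      valence = as.integer(valence), arousal = as.integer(arousal),
      quadrant = paste0("V", ifelse(quads$valence == "positive", "+", "-"),
                        "A", ifelse(quads$arousal == "high", "+", "-")))
    rec <- recording(data, fs, sc$montage, events,
                     subject = subject_id, session = session_id)
    truth <- list(active_sources = active,
                  source_labels = vapply(sc$sources[active], `[[`, "",
                                         "label"),
                  mixing = mixing, bp_multipliers = bp_mult,
                  quadrants = quads)
    list(recording = rec, truth = truth)
  })
}

#' Simulate a whole multiday study
#'
#' @param sc scenario
#' @return nested list `result[[subject]][[session]]`, each element as
#'   returned by [simulate_session()]
#' @export
simulate_study <- function(sc) {
  lapply(seq_len(sc$n_subjects), function(su)
    lapply(seq_len(sc$n_sessions), function(se)
      simulate_session(sc, su, se)))
}

#' Construct a recording
#'
#' @param data channels x samples matrix in uV
#' @param fs sampling rate in Hz
#' @param montage electrode montage matching the rows of `data`
#' @param events per-trial table with columns trial, rest_onset, stim_onset,
#'   stim_end (1-based sample indices), valence, arousal (ratings 1-5)
#' @param subject,session identifiers
#' @export
recording <- function(data, fs, montage, events, subject = NA, session = NA) {
  data <- as.matrix(data)
  if (nrow(data) != n_channels(montage))
    stopf("data has %d rows but montage has %d channels", nrow(data),
          n_channels(montage))
  ev <- events
  if (nrow(ev) > 0) {
    if (is.unsorted(ev$rest_onset)) stopf("events must be sorted")
    if (any(ev$stim_onset <= ev$rest_onset) || any(ev$stim_end < ev$stim_onset))
      stopf("event windows must be ordered rest < stim <= end")
    if (nrow(ev) > 1 && any(ev$rest_onset[-1] < ev$stim_end[-nrow(ev)]))
      stopf("events must not overlap")
    if (any(ev$stim_end > ncol(data)) || any(ev$rest_onset < 1))
      stopf("events extend beyond the recorded data")
    for (col in c("valence", "arousal"))
      if (any(!ev[[col]] %in% 1:5)) stopf("%s ratings must be in 1..5", col)
  }
  structure(list(data = data, fs = fs, montage = montage, events = ev,
                 meta = list(subject = subject, session = session)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %s session %s: %d ch x %d samples @ %g Hz, %d trials\n",
    x$meta$subject, x$meta$session, nrow(x$data), ncol(x$data), x$fs,
    nrow(x$events)))
  invisible(x)
}
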