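# shared fixtures and independent oracles

hm30 <- head_model()
m30 <- standard_montage_30(hm30)

# a reduced montage for tests where channel count is not the point
m_small <- function(n = 10) {
  montage(m30$labels[seq_len(n)], m30$positions[seq_len(n), ])
}

empty_events <- data.frame(trial = integer(0), rest_onset = integer(0),
                           stim_onset = integer(0), stim_end = integer(0),
                           valence = integer(0), arousal = integer(0))

gaussian_recording <- function(seconds = 40, fs = 125, m = m30, sd = 1,
                               seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(n_channels(m) * seconds * fs, sd = sd),
                   n_channels(m)), fs, m, empty_events)
}

# desk-scale scenario: short trials, low rate, no artifacts unless asked
fast_scenario <- function(n_subjects = 1, n_sessions = 1, n_trials = 4,
                          fs = 125, rest_s = 8, stim_s = 16,
                          sources = NULL, noise = 0.5, blinks = 0, emg = 0,
                          jitter = 0, seed = 1, ...) {
  if (is.null(sources)) {
    sources <- default_sources()
    for (i in seq_along(sources)) {
      sources[[i]]$presence_prob <- 1
      sources[[i]]$effect <- NULL
    }
  }
  scenario_spec(n_subjects, n_sessions, n_trials, fs, rest_s, stim_s,
                sources = sources,
                artifact_rates = c(blinks_per_min = blinks,
                                   emg_per_min = emg),
                sensor_noise_sd = noise, location_jitter_mm = jitter,
                hm = hm30, montage = m30, seed = seed, ...)
}

# independent brute-force oracle: exhaustive grid search of the dipole RV
# (shares only the forward model with the optimizer, not the search)
oracle_grid_rv <- function(maps, m, hm, spacing = 2, chunk = 20000) {
  maps <- as.matrix(maps)
  maps <- sweep(maps, 2, colMeans(maps))
  lim <- brain_radius(hm) - 1
  ax <- seq(-lim, lim, by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- g[sqrt(rowSums(g^2)) <= lim, , drop = FALSE]
  best <- rep(Inf, ncol(maps))
  for (i0 in seq(1, nrow(g), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1, nrow(g))
    B <- eegtrack:::lead_field_basis(g[idx, , drop = FALSE], m, hm)
    rv <- sapply(seq_len(ncol(maps)), function(j)
      eegtrack:::rv_at_locations(maps[, j], g[idx, , drop = FALSE], m, hm,
                                 B = B))
    best <- pmin(best, apply(rv, 2, min))
  }
  best
}

# feature-level component builder: noisy observations of a true source as
# the decompose/dipoles stages would deliver them
observed_component <- function(src, session, component, m, hm,
                               map_noise = 0.05, dip_noise = 2) {
  g <- lead_field(src$location, src$orientation, m, hm)
  map <- g / sqrt(sum(g^2))
  map <- map + rnorm(length(map), sd = map_noise * sqrt(mean(map^2)))
  psd_shape <- -1 * log10(1:50)          # 1/f-ish template
  for (p in src$peaks)
    psd_shape <- psd_shape +
      p$amplitude * exp(-((1:50) - p$centre)^2 / 8) / 4
  list(session = session, component = component,
       psd = psd_shape + rnorm(50, sd = 0.05),
       map = map,
       dip = src$location + rnorm(3, sd = dip_noise),
       dipolarity = 90 + runif(1, 0, 9))
}
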