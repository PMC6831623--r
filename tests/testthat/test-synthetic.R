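# synthetic multiday EEG generator

test_that("scenario validation enforces the protocol invariants", {
  expect_error(fast_scenario(n_trials = 6), "divisible by 4")
  expect_error(fast_scenario(rest_s = 0), "> 0")
  bad_rm <- default_rating_model(); bad_rm$positive[1] <- 0.5
  expect_error(fast_scenario(rating_model = bad_rm), "sum to 1")
  deep <- source_spec(c(0, 0, 85), peaks = list())
  expect_error(fast_scenario(sources = list(deep)), "inside the brain")
  hi <- source_spec(c(0, 0, 40),
                    peaks = list(list(band = "gamma", centre = 200,
                                      amplitude = 5)))
  expect_error(fast_scenario(sources = list(hi), fs = 125), "fs/2")
  expect_error(source_spec(c(0, 0, 40), presence_prob = 1.2), "presence_prob")
  expect_error(source_spec(c(0, 0, 40),
                           effect = list(dimension = "valence",
                                         band = "alpha", d = 1)),
               "no matching oscillatory peak")
})

test_that("the default protocol yields 24 trials with exact event arithmetic", {
  sc <- scenario_spec(n_subjects = 1, n_sessions = 1, seed = 2)
  expect_identical(sc$n_trials, 24L)
  ss <- simulate_session(sc, 1, 1)
  ev <- ss$recording$events
  expect_identical(nrow(ev), 24L)
  expect_true(all(ev$stim_onset - ev$rest_onset == sc$rest_s * sc$fs))
  expect_true(all(ev$stim_end - ev$stim_onset + 1 == sc$stim_s * sc$fs))
  expect_true(all(ev$valence %in% 1:5) && all(ev$arousal %in% 1:5))
  # quadrants balanced: one per quadrant per block of four
  expect_true(all(table(ev$quadrant) == 6))
})

test_that("simulation is a pure function of (seed, subject, session)", {
  sc <- fast_scenario(seed = 11)
  a <- simulate_session(sc, 1, 1)
  b <- simulate_session(sc, 1, 1)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$recording$events, b$recording$events)
  c2 <- simulate_session(sc, 1, 2)
  expect_false(identical(a$recording$data, c2$recording$data))
})

test_that("per-session presence follows the Bernoulli probability", {
  src <- list(source_spec(c(0, 0, 40),
                          peaks = list(list(band = "alpha", centre = 10,
                                            amplitude = 6)),
                          presence_prob = 0.75))
  sc <- fast_scenario(sources = src, seed = 3)
  frac <- mean(vapply(seq_len(10000), function(se)
    length(session_active_sources(sc, 1, se)) == 1, logical(1)))
  expect_lt(abs(frac - 0.75), 0.02)   # binomial 99% band at n = 10,000
  # presence_prob = 1 is always active
  sc1 <- fast_scenario(seed = 4)
  expect_identical(session_active_sources(sc1, 1, 1),
                   seq_along(sc1$sources))
})

test_that("a study has n_subjects x n_sessions recordings", {
  sc <- fast_scenario(n_subjects = 2, n_sessions = 3, n_trials = 4,
                      rest_s = 4, stim_s = 4, seed = 5)
  st <- simulate_study(sc)
  expect_length(st, 2)
  expect_true(all(lengths(st) == 3))
  expect_s3_class(st[[2]][[3]]$recording, "eeg_recording")
})

test_that("no active sources leaves artifact-free noise of the right scale", {
  src <- list(source_spec(c(0, 0, 40),
                          peaks = list(list(band = "alpha", centre = 10,
                                            amplitude = 6)),
                          presence_prob = 0))
  sc <- fast_scenario(sources = src, noise = 3, seed = 6)
  ss <- simulate_session(sc, 1, 1)
  expect_length(ss$truth$active_sources, 0)
  expect_true(all(abs(apply(ss$recording$data, 1, sd) / 3 - 1) < 0.1))
  sc0 <- fast_scenario(sources = src, noise = 0, seed = 6)
  expect_error(simulate_session(sc0, 1, 1), "degenerate")
})

test_that("an alpha-only source concentrates channel power in 8-13 Hz", {
  src <- list(source_spec(c(0, 0, 50), c(1, 0, 0), background_sd = 0,
                          peaks = list(list(band = "alpha", centre = 10,
                                            amplitude = 10))))
  sc <- fast_scenario(sources = src, noise = 0.05, seed = 7,
                      n_trials = 4, rest_s = 6, stim_s = 10)
  ss <- simulate_session(sc, 1, 1)
  ch <- which.max(apply(ss$recording$data, 1, sd))
  psd <- welch_logpsd(ss$recording$data[ch, ], sc$fs)
  freqs <- as.numeric(sub("Hz$", "", names(psd)))
  lin <- 10^psd
  bands <- eeg_bands()
  bp <- vapply(bands, function(b)
    mean(lin[freqs >= b[1] & freqs <= b[2]]), numeric(1))
  expect_true(all(bp["alpha"] >= 3 * bp[names(bp) != "alpha"]))
})

test_that("a planted d = 1 effect shifts stimulus band power with the planted sign", {
  # scaled-down protocol (8 channels, 100 Hz, 6 s rest / 12 s stimulus)
  # so that 100 replicates of 8 sessions x 24 trials stay desk-sized;
  # the cross-day t-test is applied to the planted source's band power
  # measured at the strongest channel of a one-source montage
  msub <- m_small(8)
  src <- list(source_spec(c(10, 0, 60), c(0, 0, 1), background_sd = 4,
                          peaks = list(list(band = "alpha", centre = 10,
                                            amplitude = 6)),
                          effect = list(dimension = "valence",
                                        band = "alpha", d = 1)))
  hits <- 0L
  n_rep <- 100L
  base <- scenario_spec(n_subjects = 1, n_sessions = 8, n_trials = 24,
                        fs = 100, rest_s = 6, stim_s = 12, sources = src,
                        artifact_rates = c(blinks_per_min = 0,
                                           emg_per_min = 0),
                        sensor_noise_sd = 0.5, location_jitter_mm = 0,
                        hm = hm30, montage = msub, seed = 1)
  for (rep in seq_len(n_rep)) {
    sc <- base
    sc$seed <- 1000L + rep
    vals <- list(); labs <- list()
    for (se in 1:8) {
      ss <- simulate_session(sc, 1, se)
      ch <- which.max(abs(ss$truth$mixing[, 1]))
      bp <- trial_band_power(ss$recording$data[ch, ], ss$recording$events,
                             sc$fs)
      st <- dichotomize(ss$recording$events$valence)
      keep <- st != "excluded"
      vals[[se]] <- bp$trial_means[keep, "alpha"]
      labs[[se]] <- as.character(st[keep])
    }
    v <- unlist(vals); l <- unlist(labs)
    tt <- ttest_unpaired(v[l == "positive"], v[l == "negative"])
    if (tt$t > 0) hits <- hits + 1L    # sign recovery is the contract here
  }
  expect_gte(hits / n_rep, 0.95)
})
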