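---
title: "Tracking cortical EEG sources across days: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking cortical EEG sources across days: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Scalp EEG is non-stationary across recording days: a cortical source that
is cleanly resolved on one day may be weak or absent on another, and its
spectral response to the same stimulus may differ. `eegtrack` implements a
source-level analysis chain for multiday protocols in which each session
consists of trials of a resting baseline followed by an emotion-inducing
stimulus, with self-reported valence and arousal ratings on a 1-5 scale.
The chain asks two questions: which dipolar cortical sources recur across
a subject's sessions (and across subjects), and which of their band-power
responses to the stimulus are consistently modulated by the dichotomized
emotional state.

Because the human recordings that motivate this design are not publicly
available, the package ships a synthetic multiday generator with known
ground truth. Every quantitative claim the test suite makes is made
against that generator, never against the original study's data.

## Analysis chain

Per session:

1. **Band-pass 1-50 Hz.** Zero-phase filtering implemented in the
   frequency domain by applying the squared magnitude response of an
   analog Butterworth band-pass (the exact net response of a
   forward-backward pass), with odd-reflection padding against edge
   transients. The default prototype order is 8: an order-4 band-pass
   attenuates 60 Hz mains by only ~15 dB against the 1-50 Hz band,
   whereas the order-8 response is >20 dB down at both 0.2 Hz and 60 Hz,
   which is the contract the tests enforce. `bandpass_response()` exposes
   the designed gain so tests evaluate it in closed form.
2. **Artifact subspace reconstruction (ASR)** at a cutoff of
   `k = 5` SD. Calibration diagonalizes the covariance of the cleanest
   60% of 1-s windows; 0.5-s sliding windows (50% overlap) whose
   per-principal-axis RMS exceeds its threshold have the offending axes
   reconstructed from the retained subspace (with a diagonalized
   calibration covariance the best linear reconstruction of a flagged
   axis is zero) and are blended back with a raised-cosine cross-fade.
   Two deliberate deviations in how the threshold is formed. First, the
   statistics are measured over *all* windows of the calibration
   recording, not only the cleanest 60%: the mean and SD of a
   lowest-RMS-truncated sample are biased low, and with them ASR flagged
   5-20% of perfectly clean 1/f EEG. Second, *mean + k SD* is formed on
   log-RMS (threshold = exp(mean + k SD of log windowed RMS)): windowed
   band power of drifting oscillations is approximately log-normal, and
   a linear mean + 5 SD sits near its 98th percentile, i.e. it would
   flag a few percent of genuine high-alpha periods no matter how large
   k looks - the original method fits the RMS distribution robustly for
   the same reason. With both in place ASR touches well under 1% of
   clean synthetic data (per-channel post/pre correlation >= 0.99,
   matching the ~1% bookkeeping reported for real sessions at this
   cutoff) while an injected 50-sigma burst still exceeds threshold by
   orders of magnitude.
3. **Extended-infomax ICA**, square (30 channels in, 30 components out).
   Natural-gradient updates `dW = lr (I - K tanh(u) u' - u u') W` on
   sphered data, with `K = diag(+-1)` switched by a per-pass kurtosis
   estimate; identity initialization, seeded per-pass sample permutation,
   learning-rate annealing (x0.9) on update-direction oscillation and,
   once in the fine-tuning phase, on step-size growth; stop at a weight
   change below `1e-6`. The decomposition is bit-reproducible given the
   seed. Components are ordered by projected variance and
   polarity-aligned (largest-magnitude scalp-map entry positive) so later
   clustering is sign-stable.
4. **Single-dipole fits** of every scalp map under a three-shell
   spherical head model (radii 80/85/92 mm, conductivities
   0.33/0.0042/0.33 S/m, 60 Legendre terms). The per-degree transfer
   coefficients solve the 5x5 boundary system of the layered sphere in
   radius-normalized coordinates (well conditioned to n ~ 100); the
   homogeneous limit reproduces the classical `(2n+1)/n` gains exactly,
   which the tests assert. The fit minimizes residual variance
   RV over locations in the brain sphere - coarse 10-mm grid, top-5
   seeds, Nelder-Mead refinement; the moment is unregularized least
   squares at each location. Dipolarity = 100 (1 - RV). The search is
   deterministic (no RNG). Coordinates are package-internal head-frame
   mm; no atlas mapping is attempted.
5. **Screening.** Kept iff dipolarity > 85 (strict), dipole within the
   brain sphere (boundary inclusive), and no automated artifact rule
   fires. The rules are proxies for expert visual inspection: blink
   (frontal-dominant map with > 60% of activation power below 4 Hz), EMG
   (> 50% of power above 30 Hz), and flat spectrum (log-log PSD slope
   over 2-40 Hz above -0.2). The third rule is needed because unwhitened
   mixing columns of sensor-noise components inherit spatial smoothness
   from the sphering inverse and routinely pass a dipolarity threshold;
   real screening would discard them by their featureless spectra. With
   all three rules a default synthetic session keeps ~11 of 30
   components, all planted sources among them.

Per subject:

6. **Features and clustering.** Each kept component contributes a
   log-PSD (Welch, 1-Hz bins, 1-50 Hz), a unit-norm polarity-aligned
   scalp map, and its dipole location. Each dimension is z-scored across
   the subject's components; each block is then weighted by
   `w / sqrt(block dimension)` with default weights (1, 1, 2) - without
   the dimension normalization a 50-bin PSD would dominate a 3-coordinate
   dipole block regardless of the weights, so the weights would be
   meaningless. K-means (k-means++ seeding, best of 50 seeded restarts)
   groups components across sessions; `K` defaults to a mean-silhouette
   scan over 5-15. Members farther than mean + 3 SD from their own
   centroid (statistics over that cluster's member distances) are
   relocated to the nearest other centroid if within its own 3-SD limit,
   otherwise marked outliers - one pass, then centroids are recomputed
   once. Whether the original semi-automatic procedure iterated is
   unknown; one deterministic pass is fixed and documented here.
7. **Reproducibility** of a cluster = percent of the study's sessions
   contributing at least one member (a session with several members
   counts once). 6 of 8 sessions = 75%; all 8 = 100%.

Across subjects:

8. **Canonical groups and commonality.** Greedy agglomeration of
   subject-level centroids: two centroids match iff their dipole
   centroids are within 25 mm and their scalp maps correlate at |r| >=
   0.8 (absolute, because component polarity is arbitrary); each subject
   contributes at most one cluster per group. Inter-subject commonality
   of a group = percent of subjects whose matched cluster is present in
   at least N = 6 of 8 sessions. Both thresholds are package choices
   (the original matching was qualitative); they are exposed in the
   configuration.

Statistics:

9. **Band power.** STFT with 2-s Hamming windows, 50% overlap, one-sided
   PSD in dB; five bands with inclusive edges delta 1-3, theta 4-7,
   alpha 8-13, beta 14-30, gamma 31-50 Hz, aggregated as the mean of dB
   bins per frame. Each trial's stimulus series is z-scored against the
   mean and SD of its own preceding rest frames (frames fully inside each
   segment). A rest SD below 1e-6 dB flags the trial and excludes it from
   statistics rather than producing infinities.
10. **Emotion statistics.** Ratings are dichotomized at the scale
    midpoint with strict inequalities (a rating of exactly 3 belongs to
    neither class). Subjects whose minority-class trial count falls
    strictly below mean - SD across subjects are excluded per dimension.
    The cross-day test pools trial means over sessions
    (pooled-variance Student's t, two-sided; Welch by flag); within-day
    tests and the headline p-values use label permutation with the
    add-one estimator `p = (#{|t*| >= |t|} + 1)/(n_perm + 1)` and
    `n_perm = 20000` by default. Significance markers are uncorrected
    (0.05 / 0.01) to mirror the emulated reporting; Benjamini-Hochberg
    q-values are additionally emitted and clearly labelled an extension.
    The tendency table reports, per canonical group x band x dimension,
    the percent of subjects significant at 0.05 and the percent
    significant with the majority direction, suppressing rows below 20%
    (fewer than two subjects in common). Statistics run on trial means
    rather than frame series: the tests operate on trial units, the
    frame-level alternative is retained in the exported z-series.

## The synthetic world

`scenario_spec()` defaults state the emulated protocol: 10 subjects x 8
sessions x 24 trials of 30-s rest + 60-s stimulus; 30-channel 10-20
montage on the scalp sphere (the packaged coordinate table places the
outer ring at 72 degrees inclination and interior electrodes at
great-circle midpoints, the classical 10-20 construction); sampling
250 Hz by default for desk-scale speed (500 Hz, the acquisition rate, via
`fs = 500`).

Sources are dipoles inside the brain sphere with:

- a 1/f background (exponent 1, SD 4 uV in source units; projections are
  unit-RMS across channels, so source SDs read approximately as mean
  channel microvolts);
- band-limited Gaussian oscillations (theta/alpha/beta peaks, SDs
  3.2-7.2 uV) multiplied by two log-normal envelopes: a 2-Hz burst
  envelope of depth 0.25 and a 0.02-Hz drift envelope of depth 0.5. The
  burst envelope supplies the positive excess kurtosis ICA needs while
  staying mild enough that 5-SD ASR touches only ~1% of clean data. The
  drift envelope models minute-scale band-power wander; it dominates the
  across-trial SD of log band power, which is the unit in which emotion
  effect sizes d are calibrated, and it is the nuisance component that
  per-trial rest-baseline normalization cancels (a trial's rest and
  stimulus share the slow level; the planted stimulus-locked effect does
  not cancel). Without it, d = 1 would denote a ~0.06-dB effect - far
  below what any plausible real-data effect size means;
- per-session Bernoulli presence (defaults 0.75-1.0 across the nine
  canonical sources) and 2-mm location jitter, emulating day-to-day
  dropout and re-localization;
- optionally an emotion effect (dimension, band, signed standardized
  size d). A one-off bisection finds the stimulus-window power multiplier
  whose realized across-trial standardized difference of trial-mean log
  band power equals |d|, using common random numbers under a fixed
  internal seed; at the defaults d = 1 corresponds to a ~1.7x power
  ratio between the binary states. Default effects: central-midline beta
  modulated by valence and superior-parietal beta by arousal, both d = 1
  with the positive/high state carrying more power.

Artifacts are stereotyped 400-ms biphasic blinks on a frontal-dominant
column (Poisson, 6/min - eyes-closed listening) and 20-50 Hz EMG bursts
of 0.5-2 s on temporal channels (4/min); sensor noise is 2 uV white.
Ratings are drawn per trial from pole-specific categorical distributions
peaked on {4,5} or {1,2} with P(match) = 0.8, so dichotomization is
imperfect as with real self-reports. Trials come in blocks of four, one
per emotion quadrant, shuffled within block.

Everything is a pure function of the scenario, including its seed; one
global seed derives all stage seeds through a string hash
(`derive_seed`), so a whole study or pipeline run is reproducible from
its configuration alone.

What the generator does **not** emulate: realistic cortical geometry and
the BEM/MNI pipeline (an analytic three-shell sphere replaces it -
adequate for validating the methodology, not for anatomical claims),
source connectivity, subcortical sources, inter-subject anatomical
variability beyond location jitter, and rating biases such as drift or
anchoring. A green test therefore establishes that the algorithms recover
what they claim from data of this structure - not that the original
study's numbers are reproduced, which its unreleased recordings preclude.

## Numerical and design choices worth knowing

- **Filter order** defaults to 8 (see above); `order` is exposed.
- **Series truncation**: 60 Legendre terms give ~1e-8 relative accuracy
  for sources up to 70 mm eccentricity; the expansion is evaluated with
  stable upward recurrences for P_n and P_n', written so the tangential
  term needs no 1/sqrt(1-u^2) (no pole at the dipole axis).
- **Dipole-fit determinism**: multi-start simplex from fixed grid seeds;
  ties in the coarse grid resolve by grid order. The within-brain flag is
  boundary-inclusive; the dipolarity screening threshold is strict (>).
- **k-means determinism**: restarts consume seeds derived from
  (seed, K, restart); the best run by WCSS wins with a 1e-12 tie guard.
- **Degenerate inputs**: zero-norm scalp maps, rank-deficient covariance
  (duplicated channels), constant rest baselines, single-class labels and
  zero rating variance all raise typed errors naming the offending
  object; the pipeline propagates them with the stage and session id.
- **EDF**: a minimal 16-bit codec (1-s records) is built in, as no EDF
  package is available in the target environment. The physical range is
  written per channel and re-parsed from its own ASCII header field so
  the scaling is self-consistent; round trips are exact to half a
  digitization step. The true sample count rides in the recording-id
  field so zero-padding of the final record is trimmed on read.
- **Config format** is JSON (TOML has no parser in the target
  environment); round trips are lossless and tested, including calibrated
  effect multipliers.
- **Desk scaling in tests**: replicate-heavy properties run at reduced
  sampling rates, durations and channel counts, and reduced permutation
  counts (n = 2000), with the scaling stated in each test. Protocol
  constants - 24 trials, 30 channels, band edges, 5-SD ASR cutoff, 85%
  dipolarity, 3-SD relocation, threshold 3, N = 6 of 8 days - are always
  exercised at full value. The planted-dropout property (a source present
  in 6 of 8 sessions recovers 75% reproducibility) runs at feature level:
  observed components are synthesized from true scalp projections with
  measurement noise and pass through the real clustering machinery;
  running hundreds of full ICA decompositions for this one property would
  exceed any reasonable test budget, and ICA recovery has its own
  criteria.

## Known limitations

- The spherical head model supports methodological validation only;
  location estimates are not anatomical coordinates.
- Automated artifact rules approximate expert judgment; their thresholds
  (60% low-frequency power, 50% high-frequency power, -0.2 spectral
  slope) live in the configuration and should be revisited for real data.
- The greedy cross-subject matcher is order-dependent by construction;
  the deterministic (subject, size) processing order makes results
  reproducible but a different order could merge borderline groups
  differently.
- `run_pipeline()` currently orchestrates synthetic scenarios;
  file-based studies are read with `read_session()` and can be pushed
  through the same stage functions directly.
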