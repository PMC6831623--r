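Package: eegtrack
Title: Cross-Day EEG Source Tracking and Emotion Band-Power Statistics
Version: 0.1.0
Authors@R:
    person("eegtrack", "maintainers", email = "maintainers@eegtrack.dev",
           role = c("aut", "cre"))
Description: A reusable pipeline for tracking cortical EEG sources across
    multi-day recording sessions and relating their band power to
    self-reported emotional valence and arousal. Provides band-pass
    filtering and artifact subspace reconstruction, extended-infomax
    independent component analysis, equivalent-dipole fitting under a
    three-shell spherical head model, cross-session component clustering
    with reproducibility, dipolarity and inter-subject commonality
    statistics, short-time Fourier band power with rest-baseline
    z-normalization, and dichotomized valence/arousal statistics with
    label-permutation tests. Includes a synthetic multiday EEG generator
    with known ground truth for validation, plus EDF and TSV/JSON I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
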