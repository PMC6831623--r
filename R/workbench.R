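# Pipeline orchestration: configuration, session I/O (EDF + sidecar
# event/rating TSV), the full analysis chain, and the run manifest.

#' Build a run configuration
#'
#' Every stage parameter has the emulated protocol's value as its default:
#' 1-50 Hz band-pass, ASR cutoff 5 SD, dipolarity threshold 85%, 3-SD
#' relocation, 2-s/50% STFT, 20,000 permutations, dichotomization
#' threshold 3, day criterion N = 6.
#'
#' @param scenario an `eeg_scenario` (synthetic input), or `NULL` when
#'   reading sessions from `data_dir`
#' @param data_dir directory of `sub<i>_ses<j>` EDF/TSV session pairs
#' @param out_dir output directory for reports and cache
#' @param seed global seed; all stage seeds are derived from it
#' @param ... parameter overrides (see Details in the package vignette):
#'   `lo_hz`, `hi_hz`, `filter_order`, `asr_cutoff_sd`, `ica_max_iter`,
#'   `ica_tol`, `dipolarity_min`, `K` (NULL = silhouette scan),
#'   `feature_weights`, `sd_limit`, `dip_tol_mm`, `map_corr_min`,
#'   `n_perm`, `alpha`, `min_days`, `log_level`
#' @return an `eeg_run_config` list
#' @export
run_config <- function(scenario = NULL, data_dir = NULL,
                       out_dir = tempfile("eegtrack_run_"), seed = 1L, ...) {
  cfg <- list(scenario = scenario, data_dir = data_dir, out_dir = out_dir,
              seed = as.integer(seed),
              lo_hz = 1, hi_hz = 50, filter_order = 8,
              asr_cutoff_sd = 5, asr_window_s = 0.5,
              ica_max_iter = 512, ica_tol = 1e-6,
              dipolarity_min = 85,
              K = NULL, feature_weights = c(1, 1, 2), sd_limit = 3,
              dip_tol_mm = 25, map_corr_min = 0.8,
              n_perm = 20000, alpha = c(0.05, 0.01), min_days = 6,
              log_level = "INFO")
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stopf("unknown config parameters: %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "eeg_run_config"
  cfg
}

#' Serialize / restore a configuration (JSON, lossless for scalars)
#' @param cfg an `eeg_run_config`
#' @param path JSON path
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$scenario <- if (!is.null(cfg$scenario)) scenario_to_list(cfg$scenario)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!is.null(x$scenario)) x$scenario <- scenario_from_list(x$scenario)
  cfg <- run_config()
  for (nm in names(x)) if (!is.null(x[[nm]])) cfg[[nm]] <- x[[nm]]
  # JSON reads whole numbers back as integers; numeric parameters are
  # doubles in the canonical configuration
  for (nm in c("lo_hz", "hi_hz", "filter_order", "asr_cutoff_sd",
               "asr_window_s", "ica_max_iter", "ica_tol", "dipolarity_min",
               "K", "feature_weights", "sd_limit", "dip_tol_mm",
               "map_corr_min", "n_perm", "alpha", "min_days"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- as.numeric(cfg[[nm]])
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

scenario_to_list <- function(sc) {
  list(n_subjects = sc$n_subjects, n_sessions = sc$n_sessions,
       n_trials = sc$n_trials, fs = sc$fs, rest_s = sc$rest_s,
       stim_s = sc$stim_s,
       sources = lapply(sc$sources, function(s)
         s[c("location", "orientation", "peaks", "background_exponent",
             "background_sd", "effect", "presence_prob", "label")]),
       artifact_rates = as.list(sc$artifact_rates),
       sensor_noise_sd = sc$sensor_noise_sd,
       rating_model = sc$rating_model,
       location_jitter_mm = sc$location_jitter_mm,
       head = list(radii = sc$hm$radii,
                   conductivities = sc$hm$conductivities,
                   series_terms = sc$hm$series_terms),
       seed = sc$seed)
}

scenario_from_list <- function(x) {
  hm <- head_model(unlist(x$head$radii), unlist(x$head$conductivities),
                   x$head$series_terms)
  sources <- lapply(x$sources, function(s)
    source_spec(unlist(s$location), unlist(s$orientation),
                peaks = lapply(s$peaks, as.list),
                background_exponent = s$background_exponent,
                background_sd = s$background_sd,
                effect = if (!is.null(s$effect)) as.list(s$effect),
                presence_prob = s$presence_prob, label = s$label))
  scenario_spec(x$n_subjects, x$n_sessions, x$n_trials, x$fs, x$rest_s,
                x$stim_s, sources, unlist(x$artifact_rates),
                x$sensor_noise_sd,
                lapply(x$rating_model, unlist),
                x$location_jitter_mm, hm, standard_montage_30(hm), x$seed)
}

#' Write a session to disk (EDF + sidecar event/rating TSV)
#'
#' @param rec an `eeg_recording`
#' @param prefix path prefix; writes `<prefix>.edf` and
#'   `<prefix>_events.tsv`
#' @export
write_session <- function(rec, prefix) {
  write_edf(rec$data, rec$fs, rec$montage$labels, paste0(prefix, ".edf"))
  ev <- rec$events
  df <- data.frame(trial = ev$trial,
                   rest_onset_s = (ev$rest_onset - 1) / rec$fs,
                   stim_onset_s = (ev$stim_onset - 1) / rec$fs,
                   stim_end_s = ev$stim_end / rec$fs,
                   valence = ev$valence, arousal = ev$arousal)
  utils::write.table(df, paste0(prefix, "_events.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a session (EDF + sidecar TSV), matching channels to a montage
#'
#' Channel labels are matched case-insensitively (a mismatch in case is
#' resolved and logged); unknown labels are an error.
#'
#' @param prefix path prefix as in [write_session()]
#' @param m montage to match channels against
#' @param subject,session identifiers stored in the recording
#' @export
read_session <- function(prefix, m = standard_montage_30(),
                         subject = NA, session = NA) {
  evpath <- paste0(prefix, "_events.tsv")
  if (!file.exists(evpath))
    stopf("missing sidecar event table: %s", evpath)
  edf <- read_edf(paste0(prefix, ".edf"))
  idx <- match(tolower(edf$labels), tolower(m$labels))
  if (anyNA(idx))
    stopf("channel labels not in montage: %s",
          paste(edf$labels[is.na(idx)], collapse = ", "))
  if (!identical(edf$labels, m$labels[idx]))
    log_msg("INFO", "channel labels matched case-insensitively")
  data <- matrix(0, n_channels(m), ncol(edf$data))
  data[idx, ] <- edf$data
  ev <- utils::read.delim(evpath)
  events <- data.frame(trial = ev$trial,
                       rest_onset = round(ev$rest_onset_s * edf$fs) + 1,
                       stim_onset = round(ev$stim_onset_s * edf$fs) + 1,
                       stim_end = round(ev$stim_end_s * edf$fs),
                       valence = ev$valence, arousal = ev$arousal)
  recording(data, edf$fs, m, events, subject = subject, session = session)
}

#' Write ground truth as JSON
#' @param truth ground-truth list from [simulate_session()]
#' @param path output path
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(active_sources = truth$active_sources,
         source_labels = truth$source_labels,
         mixing = truth$mixing, bp_multipliers = truth$bp_multipliers),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

log_msg <- function(level, fmt, ...) {
  lv <- c(DEBUG = 1, INFO = 2, WARN = 3)
  opt <- getOption("eegtrack.log_level", "INFO")
  if (lv[[level]] >= lv[[opt]])
    message(sprintf("[%s] %s %s", level,
                    format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full cross-day analysis pipeline
#'
#' Stage order per session: preprocessing (band-pass + ASR), extended
#' infomax ICA, dipole fitting, screening, per-component band power; then
#' per-subject clustering with outlier relocation, per-cluster emotion
#' statistics, and cross-subject commonality. Per-session intermediates
#' are cached under `out_dir/cache` and reused on re-runs with an
#' identical configuration.
#'
#' @param cfg an `eeg_run_config`
#' @return an `eeg_run_result`: subject clusters, canonical groups,
#'   commonality and tendency tables, per-subject stat reports, manifest
#' @export
run_pipeline <- function(cfg) {
  t_start <- Sys.time()
  old_opt <- options(eegtrack.log_level = cfg$log_level)
  on.exit(options(old_opt))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  cache_dir <- file.path(cfg$out_dir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  cfg_path <- file.path(cfg$out_dir, "config.json")
  write_config(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  sc <- cfg$scenario
  if (is.null(sc)) stopf("run_pipeline currently requires a scenario %s",
                         "(reading a data_dir study is done via read_session)")
  hm <- sc$hm
  n_sessions <- sc$n_sessions
  timings <- list()
  subj_components <- list()
  subj_bandpower <- list()
  for (su in seq_len(sc$n_subjects)) {
    comps <- list()
    bp_all <- list()
    for (se in seq_len(n_sessions)) {
      key <- file.path(cache_dir, sprintf("%s_s%d_e%d.rds", cfg_hash, su, se))
      if (file.exists(key)) {
        stage <- readRDS(key)
        log_msg("DEBUG", "subject %d session %d: cache hit", su, se)
      } else {
        t0 <- Sys.time()
        sim <- simulate_session(sc, su, se)
        pp <- preprocess_session(sim$recording, cfg$lo_hz, cfg$hi_hz,
                                 cfg$asr_cutoff_sd,
                                 order = cfg$filter_order)
        log_msg("DEBUG", "ASR modified fraction %.3f",
                pp$report$fraction_modified)
        dec <- extended_infomax(pp$recording,
                                seed = derive_seed(cfg$seed, "ica", su, se),
                                max_iter = cfg$ica_max_iter,
                                tol = cfg$ica_tol)
        fits <- fit_decomposition_dipoles(dec, hm)
        scr <- screen_components(dec, fits, cfg$dipolarity_min)
        kept <- scr$kept
        stage <- list(
          components = lapply(kept, function(i)
            list(session = se, component = i,
                 psd = welch_logpsd(dec$activations[i, ], dec$fs),
                 map = dec$mixing[, i],
                 dip = fits[[i]]$location,
                 dipolarity = dipolarity(fits[[i]]))),
          bandpower = lapply(stats::setNames(kept, kept), function(i)
            trial_band_power(dec$activations[i, ], dec$events, dec$fs)),
          events = dec$events,
          asr_fraction = pp$report$fraction_modified,
          ica_log = dec$log)
        saveRDS(stage, key)
        timings[[sprintf("s%d_e%d", su, se)]] <-
          as.numeric(Sys.time() - t0, units = "secs")
        log_msg("INFO", "subject %d session %d: %d/%d components kept",
                su, se, length(kept), length(fits))
      }
      comps <- c(comps, stage$components)
      bp_all[[se]] <- stage
    }
    subj_components[[su]] <- comps
    subj_bandpower[[su]] <- bp_all
  }
  # per-subject clustering
  subject_clusters <- list()
  reports <- list()
  for (su in seq_len(sc$n_subjects)) {
    feats <- ic_features(subj_components[[su]], cfg$feature_weights)
    if (!is.null(cfg$K) && cfg$K > nrow(feats$X))
      stopf("source_tracking: K = %d exceeds the %d available components",
            cfg$K, nrow(feats$X))
    cl <- cluster_subject(feats, K = cfg$K,
                          seed = derive_seed(cfg$seed, "kmeans", su))
    rel <- relocate_outliers(cl, feats, cfg$sd_limit)
    clusters <- rel$clusters
    # unique labels per subject for reporting
    labs <- make.unique(vapply(clusters, `[[`, "", "label"))
    for (k in seq_along(clusters)) clusters[[k]]$label <- labs[k]
    subject_clusters[[sprintf("sub%02d", su)]] <- clusters
    # per-cluster emotion statistics
    rep_su <- list()
    for (k in seq_along(clusters)) {
      c_k <- clusters[[k]]
      trials <- cluster_trial_table(c_k, subj_bandpower[[su]])
      if (is.null(trials)) next
      rep_su[[c_k$label]] <- emotion_stats(
        trials, n_perm = cfg$n_perm,
        seed = derive_seed(cfg$seed, "stats", su, k), alpha = cfg$alpha)
    }
    reports[[sprintf("sub%02d", su)]] <- rep_su
  }
  groups <- if (sc$n_subjects >= 2)
    match_clusters_across_subjects(subject_clusters, cfg$dip_tol_mm,
                                   cfg$map_corr_min) else list()
  min_days <- min(cfg$min_days, n_sessions)
  if (min_days < cfg$min_days)
    log_msg("INFO", "min_days clamped to the %d available sessions",
            n_sessions)
  common <- if (length(groups) > 0)
    commonality(groups, sc$n_subjects, min_days, n_sessions) else
      data.frame()
  # subjects with too few minority-class labels are excluded per dimension
  min_counts <- function(col) {
    vapply(seq_len(sc$n_subjects), function(su) {
      r <- unlist(lapply(subj_bandpower[[su]], function(st)
        st$events[[col]]))
      min(sum(r > 3), sum(r < 3))
    }, numeric(1))
  }
  kept_subjects <- lapply(c(valence = "valence", arousal = "arousal"),
                          function(col) {
      cnt <- stats::setNames(min_counts(col),
                             sprintf("sub%02d", seq_len(sc$n_subjects)))
      tryCatch(exclude_imbalanced_subjects(cnt),
               error = function(e) names(cnt))
  })
  tendency <- if (length(groups) > 0) {
    td <- lapply(names(kept_subjects), function(dim) {
      out <- tendency_commonality(reports[names(reports) %in%
                                            kept_subjects[[dim]]],
                                  groups, length(kept_subjects[[dim]]),
                                  alpha = cfg$alpha[1])
      if (nrow(out) > 0) out[out$dimension == dim, , drop = FALSE] else out
    })
    do.call(rbind, td)
  } else data.frame()
  # reports to disk
  for (su in names(subject_clusters))
    write_cluster_report(subject_clusters[[su]], n_sessions,
                         file.path(cfg$out_dir, paste0(su, "_clusters.json")))
  if (nrow(common) > 0)
    utils::write.table(common, file.path(cfg$out_dir, "commonality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(tendency) > 0)
    utils::write.table(tendency, file.path(cfg$out_dir, "tendency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  out_files <- setdiff(list.files(cfg$out_dir, pattern = "\\.(json|tsv)$",
                                  full.names = TRUE),
                       file.path(cfg$out_dir, "manifest.json"))
  manifest <- list(
    config_hash = cfg_hash,
    package_version = as.character(utils::packageVersion("eegtrack")),
    seed = cfg$seed,
    checksums = as.list(tools::md5sum(out_files)),
    timings_s = timings,
    total_s = as.numeric(Sys.time() - t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(subject_clusters = subject_clusters, groups = groups,
                 commonality = common, tendency = tendency,
                 reports = reports, manifest = manifest,
                 out_dir = cfg$out_dir),
            class = "eeg_run_result")
}

# gather the per-trial z-power table of one cluster; sessions with several
# member components contribute the average of their trial means
cluster_trial_table <- function(cluster, session_stages) {
  rows <- list()
  for (se in unique(cluster$member_session)) {
    stage <- session_stages[[se]]
    comp_ids <- cluster$member_component[cluster$member_session == se]
    mats <- lapply(comp_ids, function(i)
      stage$bandpower[[as.character(i)]]$trial_means)
    tm <- Reduce(`+`, mats) / length(mats)
    ev <- stage$events
    for (b in colnames(tm)) {
      rows[[length(rows) + 1]] <- data.frame(
        session = se, band = b, trial = ev$trial, value = tm[, b],
        valence = ev$valence, arousal = ev$arousal)
    }
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' @export
print.eeg_run_result <- function(x, ...) {
  cat(sprintf("<eeg_run_result> %d subjects, %d canonical groups (out: %s)\n",
              length(x$subject_clusters), length(x$groups), x$out_dir))
  invisible(x)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic study as EDF + TSV),
#' `all` (run the full pipeline). Each takes `--config` (JSON),
#' `--seed`, `--out`, `--log-level`.
#'
#' @param args character vector of command-line arguments
#' @export
eegtrack_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stopf("the CLI requires the optparse package")
  if (length(args) == 0)
    stopf("usage: eegtrack <simulate|all> [--config F] [--seed N] [--out D]")
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character",
                          default = "eegtrack_out"),
    optparse::make_option("--log-level", type = "character",
                          default = "INFO", dest = "log_level")))
  opt <- optparse::parse_args(parser, args[-1])
  cfg <- if (!is.null(opt$config)) read_config(opt$config) else
    run_config(scenario = scenario_spec(n_subjects = 2, n_sessions = 3,
                                        n_trials = 8, seed = opt$seed))
  cfg$seed <- opt$seed
  cfg$out_dir <- opt$out
  cfg$log_level <- opt$log_level
  if (!is.null(cfg$scenario)) cfg$scenario$seed <- opt$seed
  switch(cmd,
    simulate = {
      dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
      sc <- cfg$scenario
      for (su in seq_len(sc$n_subjects)) for (se in seq_len(sc$n_sessions)) {
        sim <- simulate_session(sc, su, se)
        prefix <- file.path(cfg$out_dir, sprintf("sub%02d_ses%02d", su, se))
        write_session(sim$recording, prefix)
        write_ground_truth(sim$truth, paste0(prefix, "_truth.json"))
      }
      write_montage(sc$montage, file.path(cfg$out_dir, "montage.tsv"))
      log_msg("INFO", "wrote %d sessions to %s",
              sc$n_subjects * sc$n_sessions, cfg$out_dir)
    },
    all = invisible(run_pipeline(cfg)),
    stopf("unknown subcommand '%s' (expected simulate or all)", cmd))
  invisible(NULL)
}
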