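# Statistics of dichotomized emotional states: rating dichotomization at
# the scale midpoint, subject exclusion for imbalanced labels, pooled
# unpaired t-tests across days, within-day label-permutation tests, rating
# regression, and the commonality-of-tendency summary table.

#' Dichotomize 1-5 ratings at the scale midpoint
#'
#' Ratings above 3 map to the positive/high state, below 3 to the
#' negative/low state; midpoint ratings (= 3) are excluded from both
#' classes (the strict inequalities leave them unlabeled).
#'
#' @param ratings data.frame with columns `valence` and `arousal`
#'   (integers 1-5), or a bare vector for a single dimension
#' @param threshold midpoint threshold (default 3)
#' @return for a data.frame: the same with `valence_state` and
#'   `arousal_state` factors in \{negative, excluded, positive\} /
#'   \{low, excluded, high\}; for a vector: a factor in
#'   \{negative, excluded, positive\}
#' @export
dichotomize <- function(ratings, threshold = 3) {
  lab <- function(x, neg, pos) {
    if (any(!x %in% 1:5)) stopf("ratings must be integers in 1..5")
    factor(ifelse(x > threshold, pos, ifelse(x < threshold, neg, "excluded")),
           levels = c(neg, "excluded", pos))
  }
  if (is.data.frame(ratings)) {
    ratings$valence_state <- lab(ratings$valence, "negative", "positive")
    ratings$arousal_state <- lab(ratings$arousal, "low", "high")
    ratings
  } else {
    lab(ratings, "negative", "positive")
  }
}

#' Exclude subjects with too few minority-class labels
#'
#' Subjects whose total minority-class trial count falls strictly below
#' (mean - SD) of that count across subjects are excluded (applied per
#' emotion dimension).
#'
#' @param counts named vector of per-subject minority-class trial counts
#' @return character vector of kept subject names
#' @export
exclude_imbalanced_subjects <- function(counts) {
  if (length(counts) < 3) stopf("need >= 3 subjects")
  thr <- mean(counts) - stats::sd(counts)
  kept <- names(counts)[counts >= thr]
  if (length(kept) == 0) stopf("exclusion rule removed every subject")
  kept
}

#' Unpaired two-sample t-test
#'
#' Two-sided pooled-variance Student's t by default (Welch via
#' `welch = TRUE`).
#'
#' @param a,b numeric vectors (>= 2 values each)
#' @param welch use the Welch unequal-variance statistic
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`
#' @export
ttest_unpaired <- function(a, b, welch = FALSE) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stopf("each group needs >= 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  d <- mean(a) - mean(b)
  if (va + vb == 0) {
    if (abs(d) < .Machine$double.eps)
      return(list(t = 0, p = 1, df = na + nb - 2,
                  mean_a = mean(a), mean_b = mean(b)))
    stopf("degenerate t-test: zero variance with unequal means")
  }
  if (welch) {
    se2a <- va / na; se2b <- vb / nb
    t <- d / sqrt(se2a + se2b)
    df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- d / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df,
       mean_a = mean(a), mean_b = mean(b))
}

#' Label-permutation test on the unpaired t statistic
#'
#' Shuffles the class labels over trials (class counts preserved) and
#' compares |t| of the observed labeling with the permutation
#' distribution. The add-one estimator
#' p = (#\{|t_perm| >= |t_obs|\} + 1) / (n_perm + 1) never returns exactly
#' zero.
#'
#' @param values numeric outcome per trial
#' @param labels two-level factor/vector (both classes present)
#' @param n_perm number of permutations (>= 100; 20000 mirrors common
#'   practice)
#' @param seed RNG seed; deterministic given seed
#' @return list with `p`, `t_obs`, `n_perm`
#' @export
permutation_test <- function(values, labels, n_perm = 20000, seed = 1L) {
  if (n_perm < 100) stopf("n_perm must be >= 100")
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  lv <- unique(as.character(labels))
  if (length(lv) != 2) stopf("permutation test needs exactly 2 classes")
  ia <- labels == lv[1]
  na <- sum(ia); nb <- sum(!ia); n <- na + nb
  if (na < 2 || nb < 2) stopf("each class needs >= 2 trials")
  t_of <- function(sel) {
    # sel: logical membership of class A
    a <- values[sel]; b <- values[!sel]
    va <- stats::var(a); vb <- stats::var(b)
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (n - 2)
    if (sp2 <= 0) return(0)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  t_obs <- t_of(ia)
  exceed <- with_seed(derive_seed(seed, "perm"), {
    sum(vapply(seq_len(n_perm), function(i) {
      sel <- logical(n)
      sel[sample.int(n, na)] <- TRUE
      abs(t_of(sel)) >= abs(t_obs) - 1e-12
    }, logical(1)))
  })
  list(p = (exceed + 1) / (n_perm + 1), t_obs = t_obs, n_perm = n_perm)
}

#' Linear regression of band power on ratings
#'
#' Pearson correlation with the two-sided p from the t transform, plus the
#' least-squares line.
#'
#' @param ratings 1-5 ratings per trial (>= 3 trials, non-zero variance)
#' @param values trial-mean band power per trial
#' @return list with `r`, `p`, `slope`, `intercept`, `n`
#' @export
rating_regression <- function(ratings, values) {
  keep <- !is.na(ratings) & !is.na(values)
  ratings <- as.numeric(ratings[keep]); values <- values[keep]
  n <- length(ratings)
  if (n < 3) stopf("regression needs >= 3 trials")
  if (stats::var(ratings) == 0) stopf("zero rating variance")
  r <- stats::cor(ratings, values)
  t <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  slope <- stats::cov(ratings, values) / stats::var(ratings)
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2), slope = slope,
       intercept = mean(values) - slope * mean(ratings), n = n)
}

#' Per-cluster, per-band emotion statistics for one subject
#'
#' Cross-day analysis pools trial means over all sessions in which the
#' cluster is present (pooled-variance unpaired t-test plus a label
#' permutation test); within-day analysis runs the permutation test on
#' each session's trials. Direction reports which binary state shows
#' power suppression (lower mean).
#'
#' @param trials data.frame with columns `session`, `band`, `value`
#'   (trial-mean z power), `valence`, `arousal` (raw ratings)
#' @param n_perm permutations for the label-shuffling test
#' @param seed RNG seed
#' @param alpha significance levels for the markers
#' @return an `eeg_stat_report` data.frame: one row per band x dimension
#'   with group means, t, parametric p, permutation p, group sizes,
#'   direction, and significance markers; per-session permutation p values
#'   are attached as an attribute `within_day`
#' @export
emotion_stats <- function(trials, n_perm = 20000, seed = 1L,
                          alpha = c(0.05, 0.01)) {
  trials <- dichotomize(trials)
  out <- list()
  within <- list()
  for (band in unique(trials$band)) {
    tb <- trials[trials$band == band & !is.na(trials$value), ]
    for (dim in c("valence", "arousal")) {
      st <- tb[[paste0(dim, "_state")]]
      pos_lab <- levels(st)[3]; neg_lab <- levels(st)[1]
      pos <- tb$value[st == pos_lab]; neg <- tb$value[st == neg_lab]
      if (length(pos) < 2 || length(neg) < 2) next
      tt <- ttest_unpaired(pos, neg)
      pt <- permutation_test(tb$value[st != "excluded"],
                             droplevels(st[st != "excluded"]),
                             n_perm = n_perm,
                             seed = derive_seed(seed, band, dim))
      key <- paste(band, dim, sep = ".")
      within[[key]] <- vapply(unique(tb$session), function(se) {
        ts <- tb[tb$session == se, ]
        sts <- ts[[paste0(dim, "_state")]]
        ok <- sts != "excluded"
        if (sum(sts == pos_lab) < 2 || sum(sts == neg_lab) < 2)
          return(NA_real_)
        permutation_test(ts$value[ok], droplevels(sts[ok]), n_perm = n_perm,
                         seed = derive_seed(seed, band, dim, se))$p
      }, numeric(1))
      out[[key]] <- data.frame(
        band = band, dimension = dim,
        mean_pos = tt$mean_a, mean_neg = tt$mean_b,
        n_pos = length(pos), n_neg = length(neg),
        t = tt$t, p_param = tt$p, p_perm = pt$p,
        direction = if (tt$mean_a < tt$mean_b)
          paste0(pos_lab, "_suppressed") else paste0(neg_lab, "_suppressed"),
        sig = if (pt$p < alpha[2]) "**" else if (pt$p < alpha[1]) "*" else "")
    }
  }
  rep <- do.call(rbind, out)
  if (is.null(rep)) return(NULL)       # no band/dimension had 2 per class
  # Benjamini-Hochberg q-values across this report (extension, clearly
  # labelled; the headline alpha markers stay uncorrected)
  rep$q_bh <- stats::p.adjust(rep$p_perm, method = "BH")
  attr(rep, "within_day") <- within
  class(rep) <- c("eeg_stat_report", class(rep))
  rep
}

#' Commonality-of-tendency table across subjects
#'
#' For every canonical source group x band x dimension: the percentage of
#' all subjects whose matched cluster shows a significant difference
#' between the binary states (permutation p < `alpha`), and the percentage
#' that are significant AND share the majority effect direction. Rows
#' below `floor_pct` (fewer than two subjects in common by default) are
#' suppressed.
#'
#' @param reports named list: per subject, the `eeg_stat_report` of each
#'   cluster (list keyed by cluster label)
#' @param groups canonical groups from [match_clusters_across_subjects()]
#' @param n_subjects total subjects
#' @param alpha significance level
#' @param floor_pct report floor in percent
#' @return data.frame: label, band, dimension, pct_significant, direction,
#'   pct_same_tendency
#' @export
tendency_commonality <- function(reports, groups, n_subjects,
                                 alpha = 0.05, floor_pct = 20) {
  rows <- list()
  for (g in groups) {
    per_subject <- lapply(g$subjects, function(su) {
      r <- reports[[su]][[g$label]]
      if (is.null(r)) return(NULL)
      r[r$p_perm < alpha, c("band", "dimension", "direction")]
    })
    sig <- do.call(rbind, per_subject)
    if (is.null(sig) || nrow(sig) == 0) next
    for (band in unique(sig$band)) for (dim in unique(sig$dimension)) {
      s <- sig[sig$band == band & sig$dimension == dim, ]
      if (nrow(s) == 0) next
      n_sig <- nrow(s)
      tab <- table(s$direction)
      n_same <- max(tab)
      rows[[length(rows) + 1]] <- data.frame(
        label = g$label, band = band, dimension = dim,
        pct_significant = 100 * n_sig / n_subjects,
        direction = names(tab)[which.max(tab)],
        pct_same_tendency = 100 * n_same / n_subjects)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame())
  out[out$pct_significant >= floor_pct, , drop = FALSE]
}
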