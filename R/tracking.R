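# Cross-session source tracking: assemble spectro-spatial features of the
# screened components of all of a subject's sessions, cluster them with
# K-means, relocate 3-SD outliers, and compute reproducibility, cluster
# dipolarity, and inter-subject commonality.

# canonical region labels (informational), package head-frame mm
canonical_regions <- function() {
  rbind(frontal_left = c(45, 35, 30), frontal_central = c(55, 0, 35),
        frontal_right = c(45, -35, 30), sensorimotor_left = c(0, 45, 55),
        central_midline = c(10, 0, 70), sensorimotor_right = c(0, -45, 55),
        occipital_left = c(-60, 25, 25), superior_parietal = c(-35, 0, 60),
        occipital_right = c(-60, -25, 25))
}

nearest_region <- function(loc) {
  reg <- canonical_regions()
  rownames(reg)[which.min(colSums((t(reg) - loc)^2))]
}

#' Assemble clustering features for screened components
#'
#' Each component contributes three blocks: log-PSD in 1-Hz bins over
#' 1-50 Hz, the unit-norm polarity-aligned scalp map, and the dipole
#' location. Every feature dimension is z-scored across the subject's
#' components, then each block is scaled by `weight / sqrt(block size)` so
#' the weights compare blocks on an equal footing regardless of their
#' dimensionality.
#'
#' @param components list with one element per component:
#'   `list(session, component, psd, map, dip, dipolarity)` (`psd` a named
#'   log-power vector, `map` the scalp-map vector, `dip` the dipole
#'   location)
#' @param weights block weights `c(psd, map, dip)`; the default `(1, 1, 2)`
#'   favours dipole location as the anatomical identity signal
#' @return an `eeg_ic_features` object: feature matrix plus component
#'   bookkeeping
#' @export
ic_features <- function(components, weights = c(1, 1, 2)) {
  if (any(weights <= 0)) stopf("block weights must be > 0")
  for (i in seq_along(components)) {
    c_i <- components[[i]]
    for (f in c("psd", "map", "dip"))
      if (is.null(c_i[[f]]))
        stopf("component %d is missing attribute '%s'", i, f)
  }
  psd <- t(vapply(components, `[[`, components[[1]]$psd, "psd"))
  map <- t(vapply(components, `[[`, components[[1]]$map, "map"))
  map <- map / sqrt(rowSums(map^2))
  # polarity alignment: largest-magnitude entry positive
  fl <- apply(map, 1, function(r) sign(r[which.max(abs(r))]))
  map <- map * fl
  dip <- t(vapply(components, function(c_i) as.numeric(c_i$dip), numeric(3)))
  zscore <- function(M) {
    mu <- colMeans(M); sd <- apply(M, 2, stats::sd)
    sd[!is.finite(sd) | sd < 1e-12] <- 1
    t((t(M) - mu) / sd)
  }
  blocks <- list(psd = zscore(psd), map = zscore(map), dip = zscore(dip))
  X <- do.call(cbind, lapply(seq_along(blocks), function(k)
    blocks[[k]] * weights[k] / sqrt(ncol(blocks[[k]]))))
  structure(list(
    X = X, blocks = blocks, weights = weights,
    session = vapply(components, `[[`, 1, "session"),
    component = vapply(components, `[[`, 1, "component"),
    dip = dip,
    map = map,
    dipolarity = vapply(components, function(c_i)
      c_i$dipolarity %||% NA_real_, numeric(1))),
    class = "eeg_ic_features")
}

#' @export
print.eeg_ic_features <- function(x, ...) {
  cat(sprintf("<eeg_ic_features> %d components x %d dims (%d sessions)\n",
              nrow(x$X), ncol(x$X), length(unique(x$session))))
  invisible(x)
}

# seeded k-means++ initialization + Lloyd iterations
kmeanspp_once <- function(X, K, max_iter = 100) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- colSums((t(X) - centers[1, ])^2)
  for (k in 2:K) {
    p <- d2 / sum(d2)
    centers[k, ] <- X[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, colSums((t(X) - centers[k, ])^2))
  }
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    D <- outer(rowSums(X^2), rowSums(centers^2), `+`) -
      2 * X %*% t(centers)
    new_assign <- max.col(-D, ties.method = "first")
    if (identical(new_assign, assign)) break
    assign <- new_assign
    for (k in seq_len(K)) {
      mem <- assign == k
      if (any(mem)) centers[k, ] <- colMeans(X[mem, , drop = FALSE])
    }
  }
  wcss <- sum((X - centers[assign, , drop = FALSE])^2)
  list(assign = assign, centers = centers, wcss = wcss)
}

#' Cluster a subject's components across sessions
#'
#' K-means with k-means++ initialization, best of `restarts` seeded runs by
#' within-cluster sum of squares. If `K` is `NULL`, it is chosen by a mean
#' silhouette scan over `k_range`.
#'
#' @param features an `eeg_ic_features`
#' @param K number of clusters (`NULL` for automatic selection)
#' @param seed RNG seed (deterministic given seed)
#' @param restarts number of k-means++ restarts
#' @param k_range candidate K values for the silhouette scan
#' @return list of `eeg_ic_cluster` objects
#' @export
cluster_subject <- function(features, K = NULL, seed = 1L, restarts = 50,
                            k_range = 5:15) {
  X <- features$X
  n <- nrow(X)
  if (is.null(K)) {
    ks <- k_range[k_range >= 2 & k_range < n]
    if (length(ks) == 0) ks <- max(2, min(5, n - 1))
    sil <- vapply(ks, function(k)
      mean_silhouette(X, kmeans_best(X, k, seed, restarts)$assign),
      numeric(1))
    K <- ks[which.max(sil)]
  }
  if (K < 2 || K > n)
    stopf("K = %d is outside the valid range 2..%d", K, n)
  fit <- kmeans_best(X, K, seed, restarts)
  make_clusters(features, fit$assign)
}

kmeans_best <- function(X, K, seed, restarts) {
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- with_seed(derive_seed(seed, "kmeans", K, r),
                     kmeanspp_once(X, K))
    if (is.null(best) || fit$wcss < best$wcss - 1e-12) best <- fit
  }
  best
}

mean_silhouette <- function(X, assign) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(n), function(i) {
    own <- assign == assign[i]; own[i] <- FALSE
    a <- if (any(own)) mean(D[i, own]) else 0
    bs <- vapply(setdiff(unique(assign), assign[i]), function(k)
      mean(D[i, assign == k]), numeric(1))
    if (length(bs) == 0) return(0)
    b <- min(bs)
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

make_clusters <- function(features, assign) {
  lapply(sort(unique(assign)), function(k) {
    mem <- which(assign == k)
    centroid <- colMeans(features$X[mem, , drop = FALSE])
    dip_c <- colMeans(features$dip[mem, , drop = FALSE])
    structure(list(
      members = mem,
      member_session = features$session[mem],
      member_component = features$component[mem],
      centroid = centroid,
      dip_centroid = dip_c,
      map_centroid = colMeans(features$map[mem, , drop = FALSE]),
      mean_dipolarity = mean(features$dipolarity[mem]),
      label = nearest_region(dip_c)),
      class = "eeg_ic_cluster")
  })
}

#' @export
print.eeg_ic_cluster <- function(x, ...) {
  cat(sprintf("<eeg_ic_cluster> %s: %d members over %d sessions (dipolarity %.1f%%)\n",
              x$label, length(x$members), length(unique(x$member_session)),
              x$mean_dipolarity))
  invisible(x)
}

#' Relocate 3-SD outlier members between clusters
#'
#' One pass: members farther than mean + `sd_limit` x SD from their own
#' cluster centroid (statistics over that cluster's member distances) are
#' moved to the nearest other centroid if they fall within that cluster's
#' mean + `sd_limit` x SD, and are otherwise marked outliers. Centroids are
#' recomputed once afterwards.
#'
#' @param clusters list of `eeg_ic_cluster` from [cluster_subject()]
#' @param features the `eeg_ic_features` the clusters were built from
#' @param sd_limit the distance limit in SDs (default 3)
#' @return `list(clusters =, outliers =)`; outliers is a vector of member
#'   indices into the feature matrix
#' @export
relocate_outliers <- function(clusters, features, sd_limit = 3) {
  X <- features$X
  assign <- integer(nrow(X))
  for (k in seq_along(clusters)) assign[clusters[[k]]$members] <- k
  cen <- t(vapply(clusters, `[[`, numeric(ncol(X)), "centroid"))
  dist_to <- function(i, k) sqrt(sum((X[i, ] - cen[k, ])^2))
  stats_k <- lapply(seq_along(clusters), function(k) {
    d <- vapply(clusters[[k]]$members, dist_to, numeric(1), k = k)
    s <- stats::sd(d)
    list(mean = mean(d), sd = if (is.finite(s)) s else 0)
  })
  limit <- vapply(stats_k, function(s) s$mean + sd_limit * s$sd, numeric(1))
  outliers <- integer(0)
  new_assign <- assign
  for (i in seq_len(nrow(X))) {
    k <- assign[i]
    if (dist_to(i, k) <= limit[k]) next
    others <- setdiff(seq_along(clusters), k)
    d_others <- vapply(others, dist_to, numeric(1), i = i)
    j <- others[which.min(d_others)]
    if (length(others) > 0 && min(d_others) <= limit[j]) {
      new_assign[i] <- j
    } else {
      new_assign[i] <- 0L
      outliers <- c(outliers, i)
    }
  }
  kept <- sort(unique(new_assign[new_assign > 0]))
  surv <- which(new_assign > 0)
  sub_feat <- subset_features(features, surv)
  out_clusters <- make_clusters(sub_feat, match(new_assign[surv], kept))
  # keep member indexing in the original feature space
  for (k in seq_along(out_clusters)) {
    out_clusters[[k]]$members <- surv[out_clusters[[k]]$members]
  }
  list(clusters = out_clusters, outliers = outliers)
}

subset_features <- function(features, idx) {
  f <- features
  f$X <- f$X[idx, , drop = FALSE]
  f$session <- f$session[idx]
  f$component <- f$component[idx]
  f$dip <- f$dip[idx, , drop = FALSE]
  f$map <- f$map[idx, , drop = FALSE]
  f$dipolarity <- f$dipolarity[idx]
  f
}

#' Reproducibility of a cluster (percent of sessions present)
#'
#' The percentage of the study's sessions in which the cluster has at least
#' one member component; multiple members from one session count once.
#'
#' @param cluster an `eeg_ic_cluster` (or anything with `member_session`)
#' @param n_sessions total number of sessions in the study
#' @export
reproducibility <- function(cluster, n_sessions) {
  if (n_sessions < 1) stopf("n_sessions must be >= 1")
  sess <- cluster$member_session
  if (length(sess) == 0) stopf("reproducibility of an empty cluster")
  100 * length(unique(sess)) / n_sessions
}

#' Match clusters across subjects into canonical groups
#'
#' Greedy agglomeration of subject-level cluster centroids: a cluster joins
#' an existing group iff its dipole centroid is within `dip_tol_mm` of the
#' group's dipole centroid and the absolute scalp-map correlation is at
#' least `map_corr_min` (absolute, since component polarity is arbitrary);
#' each subject contributes at most one cluster per group. Clusters are
#' processed in (subject, descending size) order, which makes the greedy
#' result deterministic.
#'
#' @param subject_clusters named list: per subject, the list of
#'   `eeg_ic_cluster`
#' @param dip_tol_mm dipole-centroid distance tolerance
#' @param map_corr_min minimum absolute scalp-map correlation
#' @return list of canonical groups; each has `subjects`, `clusters`
#'   (per-subject cluster), `dip_centroid`, `label`
#' @export
match_clusters_across_subjects <- function(subject_clusters,
                                           dip_tol_mm = 25,
                                           map_corr_min = 0.8) {
  if (length(subject_clusters) < 2)
    stopf("cross-subject matching needs >= 2 subjects")
  groups <- list()
  for (su in names(subject_clusters)) {
    cl <- subject_clusters[[su]]
    ord <- order(-vapply(cl, function(c_i) length(c_i$members), numeric(1)))
    for (c_i in cl[ord]) {
      cand <- which(vapply(groups, function(g) {
        if (su %in% g$subjects) return(FALSE)
        d <- sqrt(sum((g$dip_centroid - c_i$dip_centroid)^2))
        r <- abs(stats::cor(g$map_centroid, c_i$map_centroid))
        d <= dip_tol_mm && r >= map_corr_min
      }, logical(1)))
      if (length(cand) > 0) {
        dists <- vapply(cand, function(gi)
          sqrt(sum((groups[[gi]]$dip_centroid - c_i$dip_centroid)^2)),
          numeric(1))
        gi <- cand[which.min(dists)]
        g <- groups[[gi]]
        g$subjects <- c(g$subjects, su)
        g$clusters[[su]] <- c_i
        n <- length(g$subjects)
        g$dip_centroid <- ((n - 1) * g$dip_centroid + c_i$dip_centroid) / n
        # polarity-consistent running mean of the map
        s <- sign(stats::cor(g$map_centroid, c_i$map_centroid))
        g$map_centroid <- ((n - 1) * g$map_centroid +
                             s * c_i$map_centroid) / n
        g$label <- nearest_region(g$dip_centroid)
        groups[[gi]] <- g
      } else {
        groups[[length(groups) + 1]] <-
          list(subjects = su, clusters = stats::setNames(list(c_i), su),
               dip_centroid = c_i$dip_centroid,
               map_centroid = c_i$map_centroid,
               label = nearest_region(c_i$dip_centroid))
      }
    }
  }
  groups[order(-vapply(groups, function(g) length(g$subjects), numeric(1)))]
}

#' Inter-subject commonality of canonical source groups
#'
#' Per group, the percentage of all subjects whose matched cluster is
#' present in at least `min_days` of the `n_sessions` sessions (the
#' "same IC in at least N of 8 days" criterion, N = 6 by default).
#'
#' @param groups result of [match_clusters_across_subjects()]
#' @param n_subjects total number of subjects in the study
#' @param min_days day criterion N
#' @param n_sessions sessions per subject
#' @return data.frame: label, n_matched, n_meeting_criterion, commonality
#' @export
commonality <- function(groups, n_subjects, min_days = 6, n_sessions = 8) {
  if (min_days > n_sessions) stopf("min_days must be <= n_sessions")
  rows <- lapply(groups, function(g) {
    meets <- vapply(g$clusters, function(c_i)
      length(unique(c_i$member_session)) >= min_days, logical(1))
    data.frame(label = g$label, n_matched = length(g$subjects),
               n_meeting_criterion = sum(meets),
               commonality = 100 * sum(meets) / n_subjects)
  })
  do.call(rbind, rows)
}

#' Serialize a subject's cluster report to JSON
#' @param clusters list of `eeg_ic_cluster`
#' @param n_sessions sessions in the study
#' @param path output path
#' @export
write_cluster_report <- function(clusters, n_sessions, path) {
  x <- lapply(clusters, function(c_i)
    list(label = c_i$label,
         members = data.frame(session = c_i$member_session,
                              component = c_i$member_component),
         reproducibility = reproducibility(c_i, n_sessions),
         mean_dipolarity = c_i$mean_dipolarity,
         dip_centroid_mm = c_i$dip_centroid))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
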