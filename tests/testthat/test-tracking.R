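# cross-session clustering, relocation, reproducibility, commonality

fake_components <- function(centres, n_per, sessions = NULL, spread = 0.1,
                            seed = 1) {
  # components scattered around feature "centres" (list of list(psd, map,
  # dip)); returns the list ic_features() expects
  set.seed(seed)
  out <- list(); truth <- integer(0)
  k <- 0
  for (g in seq_along(centres)) for (i in seq_len(n_per)) {
    k <- k + 1
    ce <- centres[[g]]
    out[[k]] <- list(
      session = if (is.null(sessions)) i else sessions[[g]][i],
      component = k,
      psd = ce$psd + rnorm(length(ce$psd), sd = spread),
      map = ce$map + rnorm(length(ce$map), sd = spread * 0.2),
      dip = ce$dip + rnorm(3, sd = spread * 10),
      dipolarity = 92)
    truth <- c(truth, g)
  }
  list(components = out, truth = truth)
}

three_centres <- function() {
  set.seed(99)
  lapply(list(c(0, 0, 50), c(-40, 20, 30), c(30, -30, 40)), function(loc) {
    g <- lead_field(loc, rnorm(3), m30, hm30)
    list(psd = rnorm(50), map = g / sqrt(sum(g^2)), dip = loc)
  })
}

test_that("features are z-scored per dimension and identical inputs coincide", {
  fc <- fake_components(three_centres(), 6)
  f <- ic_features(fc$components)
  for (b in f$blocks) {
    expect_lt(max(abs(colMeans(b))), 1e-9)
    expect_lt(max(abs(apply(b, 2, sd) - 1)), 1e-9)
  }
  # duplicated component: distance zero
  comps <- fc$components
  comps[[2]] <- comps[[1]]; comps[[2]]$component <- 2L
  f2 <- ic_features(comps)
  expect_equal(sum((f2$X[1, ] - f2$X[2, ])^2), 0)
  bad <- fc$components; bad[[3]]$psd <- NULL
  expect_error(ic_features(bad), "component 3 is missing attribute 'psd'")
  expect_error(ic_features(fc$components, weights = c(1, 0, 1)), "> 0")
})

test_that("a dominant dipole block makes distances rank-match dipole distances", {
  set.seed(8)
  # isotropic dipole scatter so per-dimension standardization is a uniform
  # scaling and raw-mm distance ranks are preserved
  comps <- lapply(1:8, function(i)
    list(session = i, component = i, psd = rnorm(50), map = rnorm(30),
         dip = rnorm(3, sd = 20), dipolarity = 90))
  f <- ic_features(comps, weights = c(1e-6, 1e-6, 1))
  dx <- as.vector(dist(f$X))
  D <- t(vapply(comps, `[[`, numeric(3), "dip"))
  dd <- as.vector(dist(scale(D, scale = apply(D, 2, sd))))
  expect_identical(order(dx), order(dd))
})

test_that("k-means recovers planted groups and is deterministic", {
  fc <- fake_components(three_centres(), 8)
  f <- ic_features(fc$components)
  cl <- cluster_subject(f, K = 3, seed = 5)
  assign <- integer(nrow(f$X))
  for (k in seq_along(cl)) assign[cl[[k]]$members] <- k
  expect_identical(length(unique(paste(assign, fc$truth))), 3L)
  cl2 <- cluster_subject(f, K = 3, seed = 5)
  expect_identical(lapply(cl, `[[`, "members"), lapply(cl2, `[[`, "members"))
  # K = n gives singletons with zero objective
  cln <- cluster_subject(f, K = nrow(f$X), seed = 5)
  expect_true(all(lengths(lapply(cln, `[[`, "members")) == 1))
  expect_error(cluster_subject(f, K = nrow(f$X) + 1), "valid range")
  # automatic K lands on the planted number for well-separated groups
  cl_auto <- cluster_subject(f, K = NULL, seed = 5, k_range = 2:6)
  expect_length(cl_auto, 3)
})

test_that("relocation implements the mean + 3 SD rule and conserves members", {
  set.seed(10)
  # two tight planted clusters in feature space, built through the real
  # feature pipeline, plus hand-placed problem points
  n <- 12
  comps <- c(lapply(1:n, function(i)
    list(session = i, component = i, psd = c(rnorm(50, 0, 0.3)),
         map = c(rep(1, 15), rep(0, 15)) + rnorm(30, 0, 0.05),
         dip = c(30, 0, 40) + rnorm(3, sd = 1), dipolarity = 92)),
    lapply(1:n, function(i)
      list(session = i, component = n + i, psd = c(rnorm(50, 3, 0.3)),
           map = c(rep(0, 15), rep(1, 15)) + rnorm(30, 0, 0.05),
           dip = c(-40, 10, 25) + rnorm(3, sd = 1), dipolarity = 92)))
  f <- ic_features(comps)
  cl <- cluster_subject(f, K = 2, seed = 2)
  # all members within limits: nothing changes
  rel <- relocate_outliers(cl, f)
  expect_length(rel$outliers, 0)
  expect_identical(sort(unlist(lapply(rel$clusters, `[[`, "members"))),
                   seq_len(2 * n))
  # a far point 10+ SD from every centroid becomes an outlier
  comps_far <- c(comps, list(list(session = 1, component = 99,
                                  psd = rnorm(50, 40), map = rnorm(30),
                                  dip = c(0, -70, 0), dipolarity = 92)))
  f2 <- ic_features(comps_far)
  cl2 <- eegtrack:::make_clusters(f2, c(rep(1, n), rep(2, n), 1L))
  rel2 <- relocate_outliers(cl2, f2)
  expect_identical(rel2$outliers, 25L)
  # conservation: members in = members out + outliers
  all_out <- sort(c(unlist(lapply(rel2$clusters, `[[`, "members")),
                    rel2$outliers))
  expect_identical(all_out, seq_len(25L))
})

test_that("a point beyond 3 SD of its own cluster relocates to a near one", {
  # direct feature-space geometry: cluster A spread around the origin,
  # cluster B tight and far away; the probe is assigned to B but sits at
  # A's centroid, so it is far beyond B's mean + 3 SD yet well inside A's
  set.seed(11)
  nA <- 20; nB <- 10
  X <- rbind(matrix(rnorm(nA * 5), nA),
             matrix(rnorm(nB * 5, sd = 0.1), nB) +
               rep(c(20, 0, 0, 0, 0), each = nB),
             rep(0, 5))                 # the probe
  n <- nrow(X)
  f <- list(X = X, session = seq_len(n), component = seq_len(n),
            dip = matrix(rep(c(0, 0, 50), each = n), n),
            map = matrix(rnorm(n * 30), n), dipolarity = rep(92, n))
  cl <- eegtrack:::make_clusters(f, c(rep(1L, nA), rep(2L, nB), 2L))
  rel <- relocate_outliers(cl, f)
  expect_length(rel$outliers, 0)
  moved_to <- which(vapply(rel$clusters, function(c_k)
    n %in% c_k$members, logical(1)))
  a_home <- which(vapply(rel$clusters, function(c_k)
    1L %in% c_k$members, logical(1)))
  expect_identical(moved_to, a_home)
})

test_that("reproducibility counts distinct sessions", {
  mk <- function(sessions) list(member_session = sessions)
  expect_identical(reproducibility(mk(1:6), 8), 75)
  expect_identical(reproducibility(mk(1:8), 8), 100)
  expect_identical(reproducibility(mk(c(3, 3)), 8), 12.5)
  expect_error(reproducibility(mk(integer(0)), 8), "empty")
  # brute-force oracle on 1,000 randomized clusters
  set.seed(12)
  for (i in 1:1000) {
    ns <- sample(4:12, 1)
    sess <- sample.int(ns, sample(1:15, 1), replace = TRUE)
    expect_identical(reproducibility(mk(sess), ns),
                     100 * length(unique(sess)) / ns)
  }
})

test_that("cross-subject matching groups identical geometry and respects tolerances", {
  centres <- three_centres()
  subj <- lapply(1:4, function(su) {
    fc <- fake_components(centres, 6, seed = 100 + su)
    f <- ic_features(fc$components)
    cluster_subject(f, K = 3, seed = su)
  })
  names(subj) <- paste0("sub", 1:4)
  groups <- match_clusters_across_subjects(subj)
  expect_length(groups, 3)
  expect_true(all(vapply(groups, function(g) length(g$subjects), 1L) == 4))
  # 60 mm apart: never matched
  far <- list(
    sub1 = list(structure(list(members = 1L, member_session = 1,
                               member_component = 1,
                               dip_centroid = c(0, 0, 40),
                               map_centroid = rnorm(30),
                               mean_dipolarity = 95, label = "a"),
                          class = "eeg_ic_cluster")),
    sub2 = list(structure(list(members = 1L, member_session = 1,
                               member_component = 1,
                               dip_centroid = c(0, 60, 40),
                               map_centroid = rnorm(30),
                               mean_dipolarity = 95, label = "b"),
                          class = "eeg_ic_cluster")))
  expect_length(match_clusters_across_subjects(far), 2)
  # sign-flipped map with 5-mm dipole distance: matched (absolute corr)
  map <- rnorm(30)
  flip <- far
  flip$sub2[[1]]$dip_centroid <- c(0, 0, 45)
  flip$sub1[[1]]$map_centroid <- map
  flip$sub2[[1]]$map_centroid <- -map + rnorm(30, sd = 0.05)
  expect_length(match_clusters_across_subjects(flip), 1)
  expect_error(match_clusters_across_subjects(far["sub1"]), ">= 2 subjects")
})

test_that("commonality matches the worked percentages and is monotone in min_days", {
  mkgrp <- function(days_per_subject) {
    list(subjects = paste0("s", seq_along(days_per_subject)),
         clusters = setNames(lapply(days_per_subject, function(d)
           list(member_session = seq_len(d))),
           paste0("s", seq_along(days_per_subject))),
         dip_centroid = c(0, 0, 40), map_centroid = rnorm(30),
         label = "frontal_central")
  }
  g100 <- mkgrp(rep(8, 10))
  g90 <- mkgrp(c(rep(8, 9), 3))
  g50 <- mkgrp(c(rep(7, 5), rep(2, 5)))
  co <- commonality(list(g100, g90, g50), n_subjects = 10)
  expect_identical(co$commonality, c(100, 90, 50))
  prev <- rep(Inf, 3)
  for (nd in 1:8) {
    cur <- commonality(list(g100, g90, g50), 10, min_days = nd)$commonality
    expect_true(all(cur <= prev))
    prev <- cur
  }
  expect_error(commonality(list(g100), 10, min_days = 9), "min_days")
})

test_that("a source present in 6 of 8 sessions yields reproducibility 75", {
  # feature-level replication: observed components are built from the true
  # scalp projections with measurement noise, then pass through the real
  # clustering -> relocation -> reproducibility chain
  srcA <- source_spec(c(10, 0, 60), c(0, 0, 1),
                      peaks = list(list(band = "alpha", centre = 10,
                                        amplitude = 6)), label = "A")
  srcB <- source_spec(c(-50, 20, 20), c(1, 0, 0),
                      peaks = list(list(band = "theta", centre = 6,
                                        amplitude = 5)), label = "B")
  hits <- 0L
  n_rep <- 50L
  set.seed(13)
  for (rep in seq_len(n_rep)) {
    present <- sort(sample.int(8, 6))   # A appears in exactly 6 sessions
    comps <- list()
    k <- 0
    for (se in 1:8) {
      if (se %in% present) {
        k <- k + 1
        comps[[k]] <- observed_component(srcA, se, k, m30, hm30)
      }
      k <- k + 1
      comps[[k]] <- observed_component(srcB, se, k, m30, hm30)
    }
    f <- ic_features(comps)
    cl <- cluster_subject(f, K = 2, seed = rep)
    rel <- relocate_outliers(cl, f)
    reps <- vapply(rel$clusters, reproducibility, numeric(1), n_sessions = 8)
    if (any(abs(reps - 75) < 1e-9)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})
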