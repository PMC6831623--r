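# dichotomization, exclusion rule, t-tests, permutation tests, regression

test_that("dichotomization uses strict inequalities around 3", {
  expect_identical(as.character(dichotomize(c(4, 3, 1, 5, 2))),
                   c("positive", "excluded", "negative", "positive",
                     "negative"))
  df <- data.frame(valence = c(4, 3, 1), arousal = c(2, 5, 3))
  lab <- dichotomize(df)
  expect_identical(as.character(lab$valence_state),
                   c("positive", "excluded", "negative"))
  expect_identical(as.character(lab$arousal_state),
                   c("low", "high", "excluded"))
  expect_error(dichotomize(c(0, 4)), "1..5")
})

test_that("the imbalance exclusion rule is strict mean - SD", {
  counts <- c(a = 50, b = 55, c = 60, d = 58, e = 5)
  # by hand: mean 45.6, SD 23.0, threshold 22.6 -> only e excluded
  expect_identical(exclude_imbalanced_subjects(counts),
                   c("a", "b", "c", "d"))
  # all equal: SD 0, threshold = mean, strict < keeps everyone
  expect_identical(exclude_imbalanced_subjects(c(x = 10, y = 10, z = 10)),
                   c("x", "y", "z"))
  # mean 9.75, SD 0.5, threshold 9.25: the subject at 9 is excluded
  expect_identical(exclude_imbalanced_subjects(c(p = 10, q = 10, r = 10,
                                                 s = 9)),
                   c("p", "q", "r"))
  expect_error(exclude_imbalanced_subjects(c(a = 1, b = 2)), ">= 3")
})

test_that("the pooled t-test matches the textbook formula and base R", {
  res <- ttest_unpaired(c(1, 2, 3), c(4, 5, 6))
  # hand computation: pooled variance 1, se = sqrt(2/3), t = -3/se
  expect_equal(res$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$t, -3.674, tolerance = 1e-3)
  set.seed(18)
  a <- rnorm(14); b <- rnorm(17, mean = 0.4)
  ref <- t.test(a, b, var.equal = TRUE)
  res2 <- ttest_unpaired(a, b)
  expect_equal(res2$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res2$p, ref$p.value, tolerance = 1e-12)
  refw <- t.test(a, b)
  resw <- ttest_unpaired(a, b, welch = TRUE)
  expect_equal(resw$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(resw$p, refw$p.value, tolerance = 1e-12)
  # location invariance
  res3 <- ttest_unpaired(a + 5, b + 5)
  expect_equal(res3$t, res2$t, tolerance = 1e-10)
  # degenerate cases
  same <- ttest_unpaired(c(2, 2), c(2, 2))
  expect_identical(c(same$t, same$p), c(0, 1))
  expect_error(ttest_unpaired(c(2, 2), c(3, 3)), "zero variance")
  expect_error(ttest_unpaired(1, c(1, 2)), ">= 2 values")
})

test_that("the permutation test honours its contracts", {
  lab <- rep(c("A", "B"), each = 12)
  expect_identical(permutation_test(rep(2, 24), lab, n_perm = 200)$p, 1)
  # 5-SD separation: p at the add-one floor region
  set.seed(19)
  v <- c(rnorm(12), rnorm(12, mean = 5))
  res <- permutation_test(v, lab, n_perm = 2000, seed = 1)
  expect_lte(res$p, 3 / 2001)
  # class relabeling invariance
  lab2 <- ifelse(lab == "A", "B", "A")
  expect_identical(permutation_test(v, lab2, n_perm = 500, seed = 2)$p,
                   permutation_test(v, lab, n_perm = 500, seed = 2)$p)
  # determinism and the add-one estimator bound
  expect_identical(permutation_test(v, lab, n_perm = 500, seed = 3)$p,
                   permutation_test(v, lab, n_perm = 500, seed = 3)$p)
  expect_gte(permutation_test(v, lab, n_perm = 500, seed = 3)$p, 1 / 501)
  expect_error(permutation_test(v, rep("A", 24), n_perm = 200),
               "2 classes")
  expect_error(permutation_test(v, lab, n_perm = 50), ">= 100")
})

test_that("parametric and permutation p agree for Gaussian data", {
  set.seed(20)
  gaps <- vapply(1:100, function(i) {
    a <- rnorm(20); b <- rnorm(22, mean = 0.5)
    pp <- permutation_test(c(a, b), rep(c("A", "B"), c(20, 22)),
                           n_perm = 2000, seed = i)$p
    abs(pp - ttest_unpaired(a, b)$p)
  }, numeric(1))
  expect_lt(max(gaps), 0.02 + 0.02)  # 0.02 contract + MC slack at n_perm 2000
  expect_lt(mean(gaps), 0.02)
})

test_that("rating regression matches a closed-form Pearson oracle", {
  x <- c(1, 2, 2, 3, 3, 4, 4, 5, 5, 1)
  y <- c(0.3, 0.5, 0.4, 0.9, 1.1, 1.2, 1.6, 1.9, 2.2, 0.1)
  res <- rating_regression(x, y)
  # independent covariance-formula computation
  r_ref <- (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(res$r, r_ref, tolerance = 1e-12)
  ref <- cor.test(x, y)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  lmf <- lm(y ~ x)
  expect_equal(res$slope, unname(coef(lmf)[2]), tolerance = 1e-10)
  expect_equal(res$intercept, unname(coef(lmf)[1]), tolerance = 1e-10)
  # perfect line
  resp <- rating_regression(1:5, 2 * (1:5) + 1)
  expect_equal(resp$r, 1, tolerance = 1e-12)
  expect_lt(resp$p, 1e-10)
  expect_error(rating_regression(rep(3, 5), rnorm(5)), "zero rating")
  # null calibration: |r| stays small for independent data
  set.seed(21)
  small <- vapply(1:40, function(i)
    abs(rating_regression(sample(1:5, 1000, TRUE), rnorm(1000))$r),
    numeric(1))
  expect_gte(mean(small < 0.1), 0.95)
})

test_that("emotion_stats reports direction and significance per band x dimension", {
  set.seed(22)
  n_se <- 4; n_tr <- 24
  rows <- list()
  for (se in 1:n_se) {
    val <- sample(c(1, 2, 4, 5), n_tr, TRUE)
    aro <- sample(c(1, 2, 4, 5), n_tr, TRUE)
    for (b in c("alpha", "beta")) {
      v <- rnorm(n_tr)
      if (b == "beta") v <- v + ifelse(val > 3, 1.2, -1.2)  # planted valence
      rows[[length(rows) + 1]] <- data.frame(
        session = se, band = b, trial = 1:n_tr, value = v,
        valence = val, arousal = aro)
    }
  }
  trials <- do.call(rbind, rows)
  rep <- emotion_stats(trials, n_perm = 2000, seed = 4)
  beta_val <- rep[rep$band == "beta" & rep$dimension == "valence", ]
  expect_lt(beta_val$p_perm, 0.01)
  expect_identical(beta_val$sig, "**")
  expect_identical(beta_val$direction, "negative_suppressed")
  alpha_val <- rep[rep$band == "alpha" & rep$dimension == "valence", ]
  expect_gt(alpha_val$p_perm, 0.05)
  expect_true(all(c("p_param", "p_perm", "q_bh") %in% names(rep)))
  wd <- attr(rep, "within_day")
  expect_true(all(wd[["beta.valence"]] < 0.2, na.rm = TRUE))
})

test_that("tendency commonality reproduces the worked percentages", {
  mkrep <- function(p, dir)
    data.frame(band = "beta", dimension = "valence", p_perm = p,
               direction = dir,
               mean_pos = 0, mean_neg = 0, n_pos = 10, n_neg = 10,
               t = 0, p_param = p, sig = "")
  subjects <- paste0("s", 1:10)
  groups <- list(list(subjects = subjects,
                      clusters = setNames(vector("list", 10), subjects),
                      dip_centroid = c(10, 0, 70),
                      map_centroid = rnorm(30), label = "central_midline"))
  # 4 of 10 significant, all in the same direction -> (40, 40)
  reports <- setNames(lapply(1:10, function(i)
    list(central_midline = mkrep(ifelse(i <= 4, 0.01, 0.5),
                                 "negative_suppressed"))), subjects)
  out <- tendency_commonality(reports, groups, 10)
  expect_identical(c(out$pct_significant, out$pct_same_tendency), c(40, 40))
  # 4 significant, 3 sharing the direction -> (40, 30)
  reports2 <- setNames(lapply(1:10, function(i)
    list(central_midline = mkrep(
      ifelse(i <= 4, 0.01, 0.5),
      ifelse(i == 1, "positive_suppressed", "negative_suppressed")))),
    subjects)
  out2 <- tendency_commonality(reports2, groups, 10)
  expect_identical(c(out2$pct_significant, out2$pct_same_tendency), c(40, 30))
  # a single significant subject falls below the 20% report floor
  reports3 <- setNames(lapply(1:10, function(i)
    list(central_midline = mkrep(ifelse(i == 1, 0.01, 0.5),
                                 "negative_suppressed"))), subjects)
  expect_identical(nrow(tendency_commonality(reports3, groups, 10)), 0L)
})
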