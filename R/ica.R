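# Extended-infomax ICA and automated component screening.
#
# The decomposition is square (components = channels). Sub/super-Gaussian
# switching follows the extended-infomax rule: the natural-gradient update
# dW = lr (I - K tanh(u) u' - u u') W with K = diag(sign of excess
# kurtosis), re-estimated every pass on a sample of activations. Identity
# initialization and a seeded per-pass sample permutation make the result
# deterministic given the seed.

#' Sphere (whiten) a channels x samples matrix
#'
#' Symmetric whitening: sphere = C^(-1/2) from the eigendecomposition of
#' the sample covariance (denominator n - 1). The whitened covariance is
#' the identity.
#'
#' @param data channels x samples, >= 2 channels, samples > channels
#' @param tol relative eigenvalue tolerance for the rank check
#' @return list with `whitened` and `sphere`
#' @export
whiten <- function(data, tol = 1e-10) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stopf("whitening needs >= 2 channels")
  if (ncol(data) <= nrow(data)) stopf("whitening needs samples > channels")
  xc <- data - rowMeans(data)
  C <- tcrossprod(xc) / (ncol(xc) - 1)
  eg <- eigen(C, symmetric = TRUE)
  if (any(eg$values <= tol * eg$values[1]))
    stopf("rank-deficient covariance: dimension %d of %d is degenerate",
          which(eg$values <= tol * eg$values[1])[1], nrow(data))
  S <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  list(whitened = S %*% xc, sphere = S)
}

#' Extended-infomax independent component analysis
#'
#' @param data channels x samples matrix (raw, full rank) or an
#'   `eeg_recording`
#' @param seed RNG seed controlling sample permutations and kurtosis
#'   sampling; identical inputs and seed give bit-identical unmixing
#' @param max_iter maximum passes over the data
#' @param tol stopping tolerance on the Frobenius norm of the per-pass
#'   weight change
#' @param lrate initial (block-normalized) learning rate
#' @param block block size; default `min(512, floor(samples/8))`
#' @param init `"identity"` (default, deterministic) or `"random"`
#'   (seeded orthonormal start)
#' @param anneal learning-rate multiplier applied when successive updates
#'   oscillate (angle > 60 degrees)
#' @return an `eeg_decomposition`: sphere, unmixing (components x
#'   channels, applied after the sphere), mixing (its inverse; columns are
#'   scalp maps, polarity-aligned), activations, per-component projected
#'   variance share, convergence log. Components are ordered by
#'   descending projected variance.
#' @export
extended_infomax <- function(data, seed = 1L, max_iter = 512, tol = 1e-6,
                             lrate = 0.04, block = NULL, init = "identity",
                             anneal = 0.9) {
  rec <- NULL
  if (inherits(data, "eeg_recording")) { rec <- data; data <- data$data }
  data <- as.matrix(data)
  nc <- nrow(data); n <- ncol(data)
  if (nc < 2) stopf("ICA needs >= 2 channels")
  wh <- whiten(data)
  X <- wh$whitened
  block <- block %||% max(8L, min(512L, floor(n / 8)))
  nblk <- n %/% block
  ksamp <- min(6000L, n)
  with_seed(derive_seed(seed, "ext-infomax"), {
    W0 <- if (identical(init, "random")) {
      qr.Q(qr(matrix(stats::rnorm(nc * nc), nc, nc)))
    } else diag(nc)
    W <- W0
    lr <- lrate
    signs <- rep(1, nc)
    olddelta <- NULL
    restarts <- 0L
    iter <- 0L
    wchange <- Inf
    while (iter < max_iter) {
      iter <- iter + 1L
      perm <- sample.int(n)
      # kurtosis-sign estimate for the extended rule, once per pass
      us <- W %*% X[, perm[seq_len(ksamp)], drop = FALSE]
      k <- rowMeans(us^4) / rowMeans(us^2)^2 - 3
      signs <- ifelse(k >= 0, 1, -1)
      Wprev <- W
      diverged <- FALSE
      for (b in seq_len(nblk)) {
        idx <- perm[((b - 1) * block + 1):(b * block)]
        u <- W %*% X[, idx, drop = FALSE]
        y <- tanh(u)
        grad <- diag(nc) - (signs * y) %*% t(u) / block -
          tcrossprod(u) / block
        W <- W + lr * grad %*% W
        if (!all(is.finite(W)) || max(abs(W)) > 1e8) { diverged <- TRUE; break }
      }
      if (diverged) {
        restarts <- restarts + 1L
        if (restarts > 3L)
          stopf("extended infomax diverged after 3 annealed restarts")
        W <- W0; lr <- lr * 0.5; olddelta <- NULL
        next
      }
      delta <- W - Wprev
      prev_wchange <- wchange
      wchange <- sqrt(sum(delta^2))
      if (!is.null(olddelta)) {
        denom <- sqrt(sum(delta^2) * sum(olddelta^2))
        ang <- if (denom > 0) sum(delta * olddelta) / denom else 1
        # anneal on oscillation of the update direction; once in the
        # fine-tuning phase, also on growth of the step size (the noise
        # ball has been reached)
        if (ang < cos(60 * pi / 180) ||
            (wchange < 1e-3 && wchange > prev_wchange))
          lr <- lr * anneal
      }
      olddelta <- delta
      if (wchange < tol || lr < 1e-9) break
    }
    unmixing <- W
    mixing <- solve(W)                  # maps in whitened space
    # order by projected variance of each component in the original data
    A_full <- solve(W %*% wh$sphere)    # channels x components scalp maps
    act <- W %*% X
    pv <- colSums(A_full^2) * apply(act, 1, stats::var)
    ord <- order(pv, decreasing = TRUE)
    unmixing <- unmixing[ord, , drop = FALSE]
    act <- act[ord, , drop = FALSE]
    A_full <- A_full[, ord, drop = FALSE]
    pv <- pv[ord]
    # polarity: largest-magnitude scalp-map entry positive
    for (i in seq_len(nc)) {
      s <- sign(A_full[which.max(abs(A_full[, i])), i])
      if (s < 0) {
        A_full[, i] <- -A_full[, i]
        unmixing[i, ] <- -unmixing[i, ]
        act[i, ] <- -act[i, ]
      }
    }
    structure(list(sphere = wh$sphere, unmixing = unmixing,
                   mixing = A_full, activations = act,
                   proj_variance = pv / sum(pv),
                   fs = if (!is.null(rec)) rec$fs else NA_real_,
                   montage = if (!is.null(rec)) rec$montage else NULL,
                   events = if (!is.null(rec)) rec$events else NULL,
                   meta = if (!is.null(rec)) rec$meta else list(),
                   log = list(iterations = iter, wchange = wchange,
                              lrate = lr, restarts = restarts,
                              converged = wchange < tol)),
              class = "eeg_decomposition")
  })
}

#' @export
print.eeg_decomposition <- function(x, ...) {
  cat(sprintf(
    "<eeg_decomposition> %d components, %d iterations (wchange %.2e%s)\n",
    nrow(x$unmixing), x$log$iterations, x$log$wchange,
    if (x$log$converged) ", converged" else ""))
  invisible(x)
}

#' Amari separation index between two mixing matrices
#'
#' 0 for a perfect separation up to scale and permutation; < 0.1 is
#' conventionally considered a good recovery.
#'
#' @param A true mixing matrix
#' @param Ahat recovered mixing matrix
#' @export
amari_index <- function(A, Ahat) {
  P <- abs(solve(Ahat, A))
  n <- nrow(P)
  r <- sum(rowSums(P / apply(P, 1, max)) - 1)
  c <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (r + c) / (2 * n * (n - 1))
}

#' Screen components for cortical plausibility
#'
#' A component is kept iff its single-dipole fit explains more than
#' `dipolarity_min` percent of scalp-map variance, the dipole is within
#' the brain sphere, and no automated artifact rule fires. The artifact
#' rules are automated proxies for expert visual inspection: a blink rule
#' (frontal-dominant scalp map with > 60% of activation power below 4 Hz),
#' an EMG rule (> 50% of activation power above 30 Hz), and a
#' flat-spectrum rule (log-log spectral slope above `noise_slope_max` over
#' 2-40 Hz, the signature of sensor-noise components; cortical activations
#' show 1/f-like decay).
#'
#' @param dec an `eeg_decomposition` with `fs` and `montage` attached
#' @param fits list of dipole fits, one per component
#' @param dipolarity_min screening threshold in percent (strict >)
#' @param rules list of artifact-rule parameters
#'   (`blink_low_hz`, `blink_frac`, `emg_high_hz`, `emg_frac`,
#'   `frontal_labels`)
#' @return an `eeg_screened` with `kept` indices and per-component
#'   `reason` in \{kept, low_dipolarity, out_of_brain, artifact_profile\}
#' @export
screen_components <- function(dec, fits, dipolarity_min = 85,
                              rules = list()) {
  nc <- nrow(dec$unmixing)
  if (length(fits) != nc)
    stopf("need one dipole fit per component (%d fits for %d components)",
          length(fits), nc)
  r <- utils::modifyList(list(blink_low_hz = 4, blink_frac = 0.6,
                              emg_high_hz = 30, emg_frac = 0.5,
                              noise_slope_max = -0.2,
                              frontal_labels = c("Fp1", "Fp2", "F7", "F3",
                                                 "Fz", "F4", "F8")),
                         rules)
  reason <- character(nc)
  for (i in seq_len(nc)) {
    f <- fits[[i]]
    if (dipolarity(f) <= dipolarity_min) { reason[i] <- "low_dipolarity"; next }
    if (!f$within_brain) { reason[i] <- "out_of_brain"; next }
    reason[i] <- if (is_artifact_component(dec, i, r)) "artifact_profile"
    else "kept"
  }
  structure(list(kept = which(reason == "kept"), reason = reason,
                 dipolarity_min = dipolarity_min),
            class = "eeg_screened")
}

is_artifact_component <- function(dec, i, r) {
  map <- dec$mixing[, i]
  frontal <- which(dec$montage$labels %in% r$frontal_labels)
  frontal_dominant <- length(frontal) > 0 &&
    which.max(abs(map)) %in% frontal
  psd <- welch_logpsd(dec$activations[i, ], dec$fs, range = c(1, 50))
  freqs <- as.numeric(sub("Hz$", "", names(psd)))
  lin <- 10^psd
  low_frac <- sum(lin[freqs < r$blink_low_hz]) / sum(lin)
  high_frac <- sum(lin[freqs > r$emg_high_hz]) / sum(lin)
  sel <- freqs >= 2 & freqs <= 40
  slope <- stats::coef(stats::lm(psd[sel] ~ log10(freqs[sel])))[2]
  (frontal_dominant && low_frac > r$blink_frac) ||
    high_frac > r$emg_frac || slope > r$noise_slope_max
}

#' @export
print.eeg_screened <- function(x, ...) {
  cat(sprintf("<eeg_screened> kept %d of %d components\n",
              length(x$kept), length(x$reason)))
  invisible(x)
}
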