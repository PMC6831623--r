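#' Three-shell spherical head model
#'
#' Concentric-sphere volume conductor (brain, skull, scalp) with an analytic
#' Legendre-series solution for the surface potential of a current dipole.
#' This closed-form model replaces realistic (BEM) head geometry: it is
#' mesh-free and adequate for validating source-tracking methodology;
#' coordinates are package-internal head-frame millimetres (+x nose,
#' +y left ear, +z vertex, origin at the sphere centre).
#'
#' @param radii increasing radii (mm) of brain, skull and scalp boundaries
#' @param conductivities conductivities (S/m) of brain, skull, scalp
#' @param series_terms truncation order of the Legendre expansion (>= 20)
#' @return an object of class `eeg_head_model`
#' @export
head_model <- function(radii = c(80, 85, 92),
                       conductivities = c(0.33, 0.0042, 0.33),
                       series_terms = 60) {
  if (length(radii) != 3 || any(diff(radii) <= 0))
    stopf("radii must be 3 strictly increasing values")
  if (length(conductivities) != 3 || any(conductivities <= 0))
    stopf("conductivities must be 3 positive values")
  if (series_terms < 20) stopf("series_terms must be >= 20")
  hm <- structure(list(radii = as.numeric(radii),
                       conductivities = as.numeric(conductivities),
                       series_terms = as.integer(series_terms)),
                  class = "eeg_head_model")
  hm$shell_gain <- shell_gains(hm)
  hm
}

#' @export
print.eeg_head_model <- function(x, ...) {
  cat(sprintf(
    "<eeg_head_model> radii %s mm | sigma %s S/m | %d series terms\n",
    paste(x$radii, collapse = "/"),
    paste(signif(x$conductivities, 3), collapse = "/"), x$series_terms))
  invisible(x)
}

#' Brain / scalp sphere radii of a head model (mm)
#' @param hm head model
#' @export
brain_radius <- function(hm) hm$radii[1]

#' @rdname brain_radius
#' @export
scalp_radius <- function(hm) hm$radii[3]

# Per-degree transfer coefficients t_n of the layered sphere.
#
# Radial potentials per degree n: layer 1 (containing the dipole, r > b)
# carries the primary term r^-(n+1) with unit coefficient plus A1 r^n;
# layers 2 and 3 carry A_j r^n + B_j r^-(n+1). Boundary conditions are
# continuity of V and of sigma dV/dr at the two interfaces and zero radial
# current at the scalp surface. Lengths are normalized to the scalp radius
# so the 5x5 per-degree systems stay well conditioned up to n ~ 100.
shell_gains <- function(hm) {
  s <- hm$conductivities
  x1 <- hm$radii[1] / hm$radii[3]
  x2 <- hm$radii[2] / hm$radii[3]
  vapply(seq_len(hm$series_terms), function(n) {
    m <- n + 1
    A <- matrix(0, 5, 5)
    rhs <- numeric(5)
    # unknowns: A1, A2, B2, A3, B3
    A[1, ] <- c(x1^n, -x1^n, -x1^(-m), 0, 0)
    rhs[1] <- -x1^(-m)
    A[2, ] <- c(s[1] * n * x1^(n - 1), -s[2] * n * x1^(n - 1),
                s[2] * m * x1^(-(n + 2)), 0, 0)
    rhs[2] <- s[1] * m * x1^(-(n + 2))
    A[3, ] <- c(0, x2^n, x2^(-m), -x2^n, -x2^(-m))
    A[4, ] <- c(0, s[2] * n * x2^(n - 1), -s[2] * m * x2^(-(n + 2)),
                -s[3] * n * x2^(n - 1), s[3] * m * x2^(-(n + 2)))
    A[5, ] <- c(0, 0, 0, n, -m)          # V'(1) = 0 (insulating scalp)
    sol <- solve(A, rhs)
    sol[4] + sol[5]                      # V at the scalp surface, x = 1
  }, numeric(1))
}

#' Standard 30-channel 10-20 montage
#'
#' Reads the packaged 10-20/10-10 unit-sphere coordinate table and projects
#' it onto the scalp sphere of the head model.
#'
#' @param hm head model supplying the scalp radius
#' @return an `eeg_montage`: data.frame-backed list with `labels` and an
#'   N x 3 `positions` matrix in mm
#' @export
standard_montage_30 <- function(hm = head_model()) {
  path <- system.file("extdata", "montage_1020_30.tsv", package = "eegtrack",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  pos <- as.matrix(tab[, c("x", "y", "z")])
  pos <- pos / sqrt(rowSums(pos^2)) * scalp_radius(hm)
  montage(tab$label, pos)
}

#' Construct an electrode montage
#'
#' @param labels unique channel names
#' @param positions N x 3 scalp-surface coordinates in mm
#' @param tol relative tolerance for the on-scalp check
#' @export
montage <- function(labels, positions, tol = 1e-6) {
  positions <- as.matrix(positions)
  if (length(labels) < 4) stopf("montage needs at least 4 electrodes")
  if (anyDuplicated(labels)) stopf("montage labels must be unique")
  if (nrow(positions) != length(labels) || ncol(positions) != 3)
    stopf("positions must be length(labels) x 3")
  r <- sqrt(rowSums(positions^2))
  if (max(abs(r / stats::median(r) - 1)) > 10 * tol)
    stopf("electrode positions must lie on a common scalp sphere")
  rownames(positions) <- labels
  structure(list(labels = as.character(labels), positions = positions),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels: %s ...\n", length(x$labels),
              paste(utils::head(x$labels, 6), collapse = ", ")))
  invisible(x)
}

#' Number of channels in a montage
#' @param montage an `eeg_montage`
#' @export
n_channels <- function(montage) length(montage$labels)

#' Write / read a montage as TSV (label, x_mm, y_mm, z_mm)
#' @param m montage
#' @param path file path
#' @export
write_montage <- function(m, path) {
  df <- data.frame(label = m$labels, x_mm = m$positions[, 1],
                   y_mm = m$positions[, 2], z_mm = m$positions[, 3])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  montage(df$label, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]))
}

# Legendre sums used by the potential series.
# For unit vectors rd (dipole) and re (electrode), u = rd . re:
#   V = q_r * Sa(u) + (q . re) * Sb(u),
#   Sa = sum_n c_n (n P_n(u) - u P_n'(u)),  Sb = sum_n c_n P_n'(u),
# with c_n = t_n f^(n-1) / (4 pi sigma_1 R^2), f = |r_dip| / R.
legendre_sums <- function(u, fpow, hm) {
  # u: vector of cosines; fpow: matrix |u| x n_terms of f^(n-1) (recycled
  # per location); returns list(Sa, Sb) vectors.
  nt <- hm$series_terms
  t_n <- hm$shell_gain
  Pm1 <- rep(1, length(u))      # P_0
  P <- u                        # P_1
  dPm1 <- rep(0, length(u))     # P_0'
  dP <- rep(1, length(u))       # P_1'
  Sa <- numeric(length(u)); Sb <- numeric(length(u))
  for (n in seq_len(nt)) {
    cn <- t_n[n] * fpow[, n]
    Sa <- Sa + cn * (n * P - u * dP)
    Sb <- Sb + cn * dP
    # advance recurrences to degree n+1
    Pp1 <- ((2 * n + 1) * u * P - n * Pm1) / (n + 1)
    dPp1 <- dPm1 + (2 * n + 1) * P
    Pm1 <- P; P <- Pp1
    dPm1 <- dP; dP <- dPp1
  }
  list(Sa = Sa, Sb = Sb)
}

#' Average-referenced scalp potentials of a current dipole
#'
#' Evaluates the analytic three-shell series at every electrode. The result
#' is linear in the dipole moment and average-referenced (mean over
#' channels is zero).
#'
#' @param location dipole position, head-frame mm, strictly inside the brain
#'   sphere
#' @param orientation dipole moment vector (need not be unit length)
#' @param m montage
#' @param hm head model
#' @return numeric vector, one potential per channel (arbitrary units)
#' @export
lead_field <- function(location, orientation, m, hm = head_model()) {
  assert_finite(location, "location"); assert_finite(orientation, "orientation")
  G <- lead_field_basis(matrix(location, 1, 3), m, hm)
  v <- G[[1]][1, ] * orientation[1] + G[[2]][1, ] * orientation[2] +
    G[[3]][1, ] * orientation[3]
  unname(v)
}

# Vectorized lead-field basis for many candidate locations.
# Returns list of three (n_loc x n_chan) matrices: potentials for unit
# x / y / z moments, each row average-referenced.
lead_field_basis <- function(locs, m, hm = head_model()) {
  locs <- matrix(as.numeric(locs), ncol = 3)
  assert_finite(locs, "locations")
  R <- scalp_radius(hm)
  b <- sqrt(rowSums(locs^2))
  if (any(b >= brain_radius(hm)))
    stopf("dipole location outside the brain sphere (|r| = %.2f mm >= %.0f mm)",
          max(b), brain_radius(hm))
  nl <- nrow(locs); nc <- n_channels(m)
  re <- m$positions / R                       # unit electrode vectors
  rd <- locs / ifelse(b > 1e-9, b, 1)         # unit dipole vectors
  rd[b <= 1e-9, ] <- rep(c(0, 0, 1), each = sum(b <= 1e-9))
  f <- b / R
  nt <- hm$series_terms
  # f^(n-1) per location, expanded to pairs below
  fp <- outer(f, 0:(nt - 1), `^`)
  scale <- 1 / (4 * pi * hm$conductivities[1] * R^2)
  u <- rd %*% t(re)                           # nl x nc cosines
  u <- pmin(pmax(u, -1), 1)
  idx <- rep(seq_len(nl), times = nc)
  sums <- legendre_sums(as.vector(u), fp[idx, , drop = FALSE], hm)
  Sa <- matrix(sums$Sa, nl, nc) * scale
  Sb <- matrix(sums$Sb, nl, nc) * scale
  out <- lapply(1:3, function(k) {
    Vk <- rd[, k] * Sa + Sb * matrix(re[, k], nl, nc, byrow = TRUE)
    Vk - rowMeans(Vk)                         # average reference
  })
  names(out) <- c("qx", "qy", "qz")
  out
}
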