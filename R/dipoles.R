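# Equivalent current dipole fitting of IC scalp maps under the spherical
# head model. The location minimizes residual variance
# RV = ||m - m_hat||^2 / ||m||^2 over the brain sphere, with the moment
# solved by linear least squares at every candidate location (both the map
# and the model are average-referenced). The search is deterministic:
# coarse grid, top seeds, then derivative-free simplex refinement.

# residual variance of the best-moment fit at given locations
rv_at_locations <- function(map, locs, m, hm, B = NULL) {
  map <- map - mean(map)
  nm2 <- sum(map^2)
  if (is.null(B)) B <- lead_field_basis(locs, m, hm)
  y1 <- B[[1]] %*% map; y2 <- B[[2]] %*% map; y3 <- B[[3]] %*% map
  g11 <- rowSums(B[[1]]^2); g22 <- rowSums(B[[2]]^2); g33 <- rowSums(B[[3]]^2)
  g12 <- rowSums(B[[1]] * B[[2]]); g13 <- rowSums(B[[1]] * B[[3]])
  g23 <- rowSums(B[[2]] * B[[3]])
  # explained sum of squares y' G^-1 y with closed-form 3x3 inverse
  det <- g11 * (g22 * g33 - g23^2) - g12 * (g12 * g33 - g23 * g13) +
    g13 * (g12 * g23 - g22 * g13)
  det <- ifelse(abs(det) < 1e-300, 1e-300, det)
  i11 <- (g22 * g33 - g23^2); i12 <- -(g12 * g33 - g13 * g23)
  i13 <- (g12 * g23 - g13 * g22)
  i22 <- (g11 * g33 - g13^2); i23 <- -(g11 * g23 - g12 * g13)
  i33 <- (g11 * g22 - g12^2)
  expl <- (y1 * (i11 * y1 + i12 * y2 + i13 * y3) +
             y2 * (i12 * y1 + i22 * y2 + i23 * y3) +
             y3 * (i13 * y1 + i23 * y2 + i33 * y3)) / det
  pmin(pmax(1 - expl / nm2, 0), 1)
}

coarse_grid <- function(hm, spacing) {
  lim <- brain_radius(hm) - 1
  ax <- seq(-lim, lim, by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g[sqrt(rowSums(g^2)) <= lim, , drop = FALSE]
}

#' Fit a single equivalent dipole to a scalp map
#'
#' @param scalp_map per-channel vector (one column of the mixing matrix)
#' @param m montage matching the map
#' @param hm head model
#' @param grid_mm coarse-grid spacing in mm
#' @param n_seeds number of coarse-grid seeds refined by Nelder-Mead
#' @param tol convergence tolerance on RV for the local refinement
#' @return an `eeg_dipole_fit` with location (mm), moment, residual
#'   variance, dipolarity (percent) and the within-brain flag
#' @export
fit_single_dipole <- function(scalp_map, m, hm = head_model(),
                              grid_mm = 10, n_seeds = 5, tol = 1e-6) {
  scalp_map <- as.numeric(scalp_map)
  if (length(scalp_map) != n_channels(m))
    stopf("scalp map length %d does not match montage size %d",
          length(scalp_map), n_channels(m))
  if (sqrt(sum(scalp_map^2)) == 0) stopf("scalp map has zero norm")
  key <- sprintf("grid/%g/%d/%s", grid_mm, n_channels(m),
                 paste(hm$radii, collapse = "-"))
  grid <- cache_get_or(paste0(key, "/pts"), function() coarse_grid(hm, grid_mm))
  rv <- rv_at_locations(scalp_map, grid, m, hm)
  seeds <- grid[order(rv)[seq_len(min(n_seeds, nrow(grid)))], , drop = FALSE]
  lim <- brain_radius(hm) * (1 - 1e-9)
  obj <- function(loc) {
    r <- sqrt(sum(loc^2))
    pen <- 0
    if (r > lim) { loc <- loc * lim / r; pen <- (r - lim) * 1e-3 }
    rv_at_locations(scalp_map, matrix(loc, 1), m, hm) + pen
  }
  best <- NULL
  for (s in seq_len(nrow(seeds))) {
    o <- stats::optim(seeds[s, ], obj, method = "Nelder-Mead",
                      control = list(reltol = tol * 1e-2, maxit = 400))
    if (is.null(best) || o$value < best$value) best <- o
  }
  loc <- best$par
  r <- sqrt(sum(loc^2))
  if (r > lim) loc <- loc * lim / r
  # moment by least squares at the final location
  map0 <- scalp_map - mean(scalp_map)
  B <- lead_field_basis(matrix(loc, 1), m, hm)
  G <- cbind(B[[1]][1, ], B[[2]][1, ], B[[3]][1, ])
  q <- solve(crossprod(G), crossprod(G, map0))
  fitted <- as.vector(G %*% q)
  rv_final <- sum((map0 - fitted)^2) / sum(map0^2)
  dipole_fit(loc, as.vector(q), rv_final, hm,
             log = list(seeds = nrow(seeds), grid_points = nrow(grid),
                        optim_value = best$value))
}

# constructor shared by the optimizer and by tests
dipole_fit <- function(location, moment, residual_variance, hm,
                       log = list()) {
  structure(list(location = as.numeric(location),
                 moment = as.numeric(moment),
                 residual_variance = residual_variance,
                 dipolarity = 100 * (1 - residual_variance),
                 within_brain = is_within_brain(location, hm),
                 log = log),
            class = "eeg_dipole_fit")
}

#' @export
print.eeg_dipole_fit <- function(x, ...) {
  cat(sprintf(
    "<eeg_dipole_fit> at (%.1f, %.1f, %.1f) mm, dipolarity %.2f%%%s\n",
    x$location[1], x$location[2], x$location[3], x$dipolarity,
    if (x$within_brain) "" else " (outside brain)"))
  invisible(x)
}

#' Dipolarity of a fit (percent of map variance explained)
#' @param fit an `eeg_dipole_fit`
#' @export
dipolarity <- function(fit) 100 * (1 - fit$residual_variance)

#' Is a location inside the brain sphere (boundary inclusive)?
#' @param location 3-vector mm
#' @param hm head model
#' @export
is_within_brain <- function(location, hm = head_model()) {
  assert_finite(location, "location")
  sqrt(sum(location^2)) <= brain_radius(hm)
}

#' Fit dipoles to every component of a decomposition
#'
#' @param dec an `eeg_decomposition` with montage attached
#' @param hm head model
#' @param ... passed to [fit_single_dipole()]
#' @return list of fits, one per component
#' @export
fit_decomposition_dipoles <- function(dec, hm = head_model(), ...) {
  lapply(seq_len(ncol(dec$mixing)), function(i)
    fit_single_dipole(dec$mixing[, i], dec$montage, hm, ...))
}

#' Serialize dipole fits to JSON
#' @param fits list of `eeg_dipole_fit`
#' @param path output path
#' @export
write_dipole_fits <- function(fits, path) {
  x <- lapply(fits, function(f)
    list(location_mm = f$location, moment = f$moment,
         residual_variance = f$residual_variance,
         dipolarity = f$dipolarity, within_brain = f$within_brain))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
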