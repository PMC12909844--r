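#' Site positions on the latent niche axes
#'
#' The scaled latent field values per site (each axis divided by its
#' across-site standard deviation, see [scaled_latents()]), i.e. the site
#' coordinates in the hidden niche space.
#'
#' @param fit an [fit_gllvm()] result with at least one latent variable.
#' @return n x L matrix of scaled positions (columns `LV1`, `LV2`, ...).
#' @export
site_niche_positions <- function(fit) {
  scaled_latents(fit)$U
}

#' Define a niche space with an evaluation grid
#'
#' Builds the rectilinear grid on the first two latent axes over the
#' bounding box of the site positions, expanded by a margin, on which
#' species occurrence densities are evaluated.
#'
#' @param positions site positions (n x >= 2), e.g.
#'   [site_niche_positions()].
#' @param n_grid grid points per axis.
#' @param margin fractional bounding-box expansion per side.
#' @return object of class `niche_space`: list with `positions`, `grid_x`,
#'   `grid_y`.
#' @export
niche_space <- function(positions, n_grid = 200, margin = 0.1) {
  positions <- as.matrix(positions)
  if (ncol(positions) < 2) stopf("need at least two latent axes")
  if (!all(is.finite(positions))) stopf("positions must be finite")
  rx <- range(positions[, 1L]); ry <- range(positions[, 2L])
  ex <- diff(rx) * margin; ey <- diff(ry) * margin
  ex <- max(ex, 1e-6); ey <- max(ey, 1e-6)
  structure(list(
    positions = positions,
    grid_x = seq(rx[1L] - ex, rx[2L] + ex, length.out = n_grid),
    grid_y = seq(ry[1L] - ey, ry[2L] + ey, length.out = n_grid)
  ), class = "niche_space")
}

silverman_bw <- function(x) {
  n <- length(x)
  s <- min(sd(x), iqr_linear(x) / 1.34)
  if (!is.finite(s) || s <= 0) s <- max(sd(x), 1e-3)
  if (s <= 0) s <- 1e-3
  0.9 * s * n^(-1 / 5)
}

kde_grid <- function(px, py, gx, gy, bw) {
  Dx <- dnorm(outer(gx, px, "-"), sd = bw[1L])
  Dy <- dnorm(outer(gy, py, "-"), sd = bw[2L])
  (Dx %*% t(Dy)) / length(px)
}

#' Species niche centre by kernel density
#'
#' The niche centre of a species is the position of highest
#' kernel-density-estimated occurrence in the niche space: a Gaussian
#' product kernel is placed at the niche positions of the occupied sites,
#' the density is evaluated on the niche-space grid, and the centre is the
#' arg-max grid point (ties broken by lowest grid index).
#'
#' @param space a [niche_space()].
#' @param occupied logical or 0/1 vector over sites: where the species was
#'   detected.
#' @param bandwidth optional length-2 kernel sd per axis; default
#'   Silverman's rule on the occupied positions.
#' @return list with `centre` (length-2 coordinates), `index` (grid
#'   indices) and `bandwidth`.
#' @export
species_niche_centre <- function(space, occupied, bandwidth = NULL) {
  if (!inherits(space, "niche_space")) stopf("`space` must be a niche_space")
  occupied <- as.logical(occupied)
  if (length(occupied) != nrow(space$positions))
    stopf("`occupied` must have one entry per site")
  if (!any(occupied)) stopf("species has no occupied sites")
  px <- space$positions[occupied, 1L]
  py <- space$positions[occupied, 2L]
  if (is.null(bandwidth)) {
    bandwidth <- if (length(px) > 1L) c(silverman_bw(px), silverman_bw(py))
    else rep(diff(range(space$grid_x)) / 50, 2L)
  }
  bandwidth <- rep_len(bandwidth, 2L)
  dens <- kde_grid(px, py, space$grid_x, space$grid_y, bandwidth)
  k <- which.max(dens)                    # first maximum = lowest index
  ij <- arrayInd(k, dim(dens))
  list(centre = c(space$grid_x[ij[1L]], space$grid_y[ij[2L]]),
       index = ij[1, ], bandwidth = bandwidth)
}

#' Niche centres for all species
#'
#' @param space a [niche_space()].
#' @param detections a [detection_matrix()] whose sites match the niche
#'   positions (same order).
#' @param bandwidth optional shared bandwidth passed on to
#'   [species_niche_centre()].
#' @return matrix (species x 2) of niche-centre coordinates.
#' @export
species_niche_centres <- function(space, detections, bandwidth = NULL) {
  occ <- detections$mat > 0
  if (ncol(occ) != nrow(space$positions))
    stopf("detections and niche positions cover different site sets")
  out <- t(vapply(seq_len(nrow(occ)), function(j) {
    species_niche_centre(space, occ[j, ], bandwidth)$centre
  }, numeric(2)))
  dimnames(out) <- list(rownames(detections$mat), c("LV1", "LV2"))
  out
}

#' Classify niche centres into zero-line regions
#'
#' Assigns each species to the quadrant of the niche space delimited by the
#' zero-value lines of the two latent axes. Because latent signs are only
#' identified up to reflection, the mapping from sign quadrants to region
#' names is a declared convention; a coordinate exactly on a zero line
#' counts as positive.
#'
#' @param centres species x 2 matrix of niche-centre coordinates.
#' @param convention named character vector mapping quadrant codes
#'   (`"Q++"`, `"Q+-"`, `"Q-+"`, `"Q--"`) to region names; defaults to the
#'   quadrant codes themselves.
#' @return list with `labels` (region per species) and `proportions`
#'   (fraction of species per region, summing to 1).
#' @export
classify_niche_regions <- function(centres, convention = NULL) {
  centres <- as.matrix(centres)
  if (ncol(centres) != 2) stopf("`centres` must have two columns")
  quad <- paste0("Q",
                 ifelse(centres[, 1L] >= 0, "+", "-"),
                 ifelse(centres[, 2L] >= 0, "+", "-"))
  if (!is.null(convention)) {
    missing_q <- setdiff(unique(quad), names(convention))
    if (length(missing_q) > 0)
      stopf("convention lacks quadrant(s): %s",
            paste(missing_q, collapse = ", "))
    quad <- unname(convention[quad])
  }
  props <- table(quad) / length(quad)
  list(labels = setNames(quad, rownames(centres)),
       proportions = setNames(as.numeric(props), names(props)))
}

#' Interpolate latent fields onto a geographic grid
#'
#' Gaussian-process conditional mean of each (scaled) latent field on a
#' rectilinear grid over the site bounding box, under the fitted Matern
#' correlation — the same kernel used for prediction at new sites.
#'
#' @param fit an [fit_gllvm()] result with latent variables.
#' @param n_grid grid points per axis.
#' @param margin fractional bounding-box expansion.
#' @param grid_x,grid_y optional explicit grid axes (override `n_grid`,
#'   `margin`).
#' @return object of class `latent_surface`: list with `x`, `y` (grid
#'   axes) and `z` (array `length(x)` x `length(y)` x L of field values).
#' @export
interpolate_latent_surface <- function(fit, n_grid = 200, margin = 0.1,
                                       grid_x = NULL, grid_y = NULL) {
  L <- fit$spec$n_latent
  if (L == 0) stopf("model has no latent variables")
  sc <- scaled_latents(fit)
  if (is.null(grid_x)) {
    rx <- range(fit$coords[, 1L]); ex <- max(diff(rx) * margin, 1e-6)
    grid_x <- seq(rx[1L] - ex, rx[2L] + ex, length.out = n_grid)
  }
  if (is.null(grid_y)) {
    ry <- range(fit$coords[, 2L]); ey <- max(diff(ry) * margin, 1e-6)
    grid_y <- seq(ry[1L] - ey, ry[2L] + ey, length.out = n_grid)
  }
  if (length(grid_x) == 0 || length(grid_y) == 0) stopf("empty grid")
  gpts <- cbind(rep(grid_x, times = length(grid_y)),
                rep(grid_y, each = length(grid_x)))
  n <- nrow(fit$coords)
  d_train <- site_distances(fit$coords, method = fit$distance)
  z <- array(NA_real_, c(length(grid_x), length(grid_y), L),
             dimnames = list(NULL, NULL, colnames(fit$U)))
  chunk <- 20000L
  for (l in seq_len(L)) {
    R_tr <- matern_correlation(d_train, fit$ranges[l], fit$smoothness) +
      diag(1e-8, n)
    w <- solve(R_tr, sc$U[, l])
    vals <- numeric(nrow(gpts))
    for (start in seq(1L, nrow(gpts), by = chunk)) {
      sel <- start:min(start + chunk - 1L, nrow(gpts))
      dc <- site_distances(gpts[sel, , drop = FALSE], fit$coords,
                           method = fit$distance)
      vals[sel] <- matern_correlation(dc, fit$ranges[l], fit$smoothness) %*% w
    }
    z[, , l] <- matrix(vals, length(grid_x), length(grid_y))
  }
  structure(list(x = grid_x, y = grid_y, z = z), class = "latent_surface")
}

#' Extract zero-value boundaries from latent surfaces
#'
#' Marching-squares zero-level contours of each interpolated latent field:
#' the polylines are hypothetical biogeographic boundaries where community
#' composition is expected to turn over. A field whose values do not change
#' sign yields no boundary; a field with a broad near-zero area (at least
#' `broad_zero_frac` of grid cells within `broad_zero_eps` standard
#' deviations of zero) is flagged as having no interpretable boundary
#' lines.
#'
#' @param surface a [interpolate_latent_surface()] result.
#' @param min_vertices contours with fewer vertices are discarded.
#' @param broad_zero_frac grid fraction triggering the broad-zero-area
#'   flag.
#' @param broad_zero_eps near-zero half-width as a multiple of the field
#'   sd.
#' @return object of class `boundary_set`: list with `boundaries` (per LV,
#'   a list of data frames with `x`, `y` vertices) and `notes` (per LV:
#'   `"ok"`, `"no-sign-change"` or `"broad-zero-area"`).
#' @export
extract_zero_boundaries <- function(surface, min_vertices = 5,
                                    broad_zero_frac = 0.2,
                                    broad_zero_eps = 0.1) {
  if (!inherits(surface, "latent_surface"))
    stopf("`surface` must be a latent_surface")
  L <- dim(surface$z)[3L]
  boundaries <- vector("list", L)
  notes <- character(L)
  for (l in seq_len(L)) {
    zmat <- surface$z[, , l]
    s <- sd(zmat)
    if (s == 0 || all(zmat > 0) || all(zmat < 0)) {
      boundaries[[l]] <- list()
      notes[l] <- "no-sign-change"
      next
    }
    near0 <- mean(abs(zmat) < broad_zero_eps * s)
    if (near0 >= broad_zero_frac) {
      boundaries[[l]] <- list()
      notes[l] <- "broad-zero-area"
      next
    }
    cl <- grDevices::contourLines(surface$x, surface$y, zmat, levels = 0)
    keep <- Filter(function(cc) length(cc$x) >= min_vertices, cl)
    boundaries[[l]] <- lapply(keep, function(cc)
      data.frame(x = cc$x, y = cc$y))
    notes[l] <- "ok"
  }
  names(boundaries) <- names(notes) <- dimnames(surface$z)[[3L]]
  structure(list(boundaries = boundaries, notes = notes),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("<boundary_set>\n")
  for (nm in names(x$boundaries))
    cat(sprintf("  %s: %d polyline(s) [%s]\n", nm,
                length(x$boundaries[[nm]]), x$notes[[nm]]))
  invisible(x)
}
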