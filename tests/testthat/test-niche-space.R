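make_fitted_toy <- function(seed = 131, n = 80, S = 25) {
  tr <- generate_communities(synthetic_config(
    n_sites = n, n_species = S, n_latent = 2, matern_ranges = c(0.3, 0.6),
    seed = seed))
  fit <- suppressWarnings(fit_gllvm(
    tr$detections, tr$sites,
    model_spec(c("temperature", "salinity"), n_latent = 2),
    gllvm_control(seed = 1, maxit = 500)))
  list(tr = tr, fit = fit)
}

test_that("site niche positions are the unit-sd scaled latent fields", {
  toy <- make_fitted_toy()
  pos <- site_niche_positions(toy$fit)
  expect_equal(unname(apply(pos, 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_identical(rownames(pos), toy$fit$site_ids)
  s <- apply(toy$fit$U, 2, sd)
  expect_equal(pos, sweep(toy$fit$U, 2, s, "/"), tolerance = 1e-12)

  fit0 <- suppressWarnings(fit_gllvm(
    toy$tr$detections, toy$tr$sites,
    model_spec(c("temperature", "salinity"), n_latent = 0),
    gllvm_control(seed = 1, maxit = 200)))
  expect_error(site_niche_positions(fit0), "no latent")
})

test_that("kernel-density niche centres behave like gaussian mixture modes", {
  pos <- rbind(c(-0.5, 0), c(0.5, 0), c(3, 3), c(-3, -3))
  space <- niche_space(pos, n_grid = 121)

  # a single occupied site: centre at (the grid point nearest) that site
  one <- species_niche_centre(space, c(TRUE, FALSE, FALSE, FALSE))
  gap <- c(diff(space$grid_x[1:2]), diff(space$grid_y[1:2]))
  expect_lt(abs(one$centre[1] - (-0.5)), gap[1])
  expect_lt(abs(one$centre[2] - 0), gap[2])

  # two symmetric sites with bandwidth >= separation: mode at the midpoint
  two <- species_niche_centre(space, c(TRUE, TRUE, FALSE, FALSE),
                              bandwidth = c(1.5, 1.5))
  expect_lt(abs(two$centre[1]), gap[1])
  expect_lt(abs(two$centre[2]), gap[2])

  expect_error(species_niche_centre(space, rep(FALSE, 4)), "no occupied")
})

test_that("niche centres stay inside the convex hull of occupied sites", {
  set.seed(17)
  for (rep in 1:5) {
    pos <- matrix(rnorm(40), 20, 2)
    space <- niche_space(pos, n_grid = 101)
    occ <- seq_len(20) %in% sample(20, 8)
    ctr <- species_niche_centre(space, occ)$centre
    hull <- grDevices::chull(pos[occ, ])
    hx <- pos[occ, ][hull, ]
    # point-in-polygon with tolerance of one grid cell
    gap <- max(diff(space$grid_x[1:2]), diff(space$grid_y[1:2]))
    d2hull <- min(sqrt(rowSums(sweep(hx, 2, ctr)^2)))
    inside <- sp_in_poly(ctr, hx)
    expect_true(inside || d2hull < 2 * gap)
  }
})

test_that("centre estimation ignores species order and unoccupied sites", {
  set.seed(23)
  pos <- matrix(rnorm(30), 15, 2)
  occ <- c(rep(TRUE, 6), rep(FALSE, 9))
  space <- niche_space(pos, n_grid = 101)
  c1 <- species_niche_centre(space, occ, bandwidth = c(0.5, 0.5))$centre
  # adding unoccupied sites must not move the centre (same grid)
  pos2 <- rbind(pos, matrix(0.1, 4, 2))
  space2 <- niche_space(pos2, n_grid = 101)
  space2$grid_x <- space$grid_x; space2$grid_y <- space$grid_y
  c2 <- species_niche_centre(space2, c(occ, rep(FALSE, 4)),
                             bandwidth = c(0.5, 0.5))$centre
  expect_equal(c1, c2)
})

test_that("quadrant classification assigns planted species exactly", {
  centres <- rbind(sub = c(1, 1), tempk = c(-1, 1),
                   other = c(-1, -1), arctic = c(1, -1), edge = c(0, 1))
  out <- classify_niche_regions(centres)
  expect_identical(unname(out$labels),
                   c("Q++", "Q-+", "Q--", "Q+-", "Q++"))  # >=0 counts +
  expect_equal(sum(out$proportions), 1)

  conv <- c("Q++" = "subtropical", "Q-+" = "temperate",
            "Q--" = "subarctic", "Q+-" = "inland")
  named <- classify_niche_regions(centres, convention = conv)
  expect_identical(unname(named$labels[1]), "subtropical")
  expect_equal(unname(named$proportions[names(named$proportions) ==
                                          "subtropical"]), 2 / 5)
})

test_that("latent surfaces interpolate the fitted values and decay far away", {
  toy <- make_fitted_toy(seed = 141, n = 50, S = 20)
  fit <- toy$fit
  # a grid whose axes pass exactly through the first site
  gx <- sort(c(fit$coords[1, 1], seq(min(fit$coords[, 1]),
                                     max(fit$coords[, 1]), length.out = 21)))
  gy <- sort(c(fit$coords[1, 2], seq(min(fit$coords[, 2]),
                                     max(fit$coords[, 2]), length.out = 21)))
  surf <- interpolate_latent_surface(fit, grid_x = gx, grid_y = gy)
  ix <- which(gx == fit$coords[1, 1])[1]
  iy <- which(gy == fit$coords[1, 2])[1]
  sc <- scaled_latents(fit)
  for (l in 1:2)
    expect_equal(unname(surf$z[ix, iy, l]), unname(sc$U[1, l]),
                 tolerance = 1e-6)

  far <- interpolate_latent_surface(fit, grid_x = c(100, 101),
                                    grid_y = c(100, 101))
  expect_lt(max(abs(far$z)), 1e-3)
  expect_error(interpolate_latent_surface(fit, grid_x = numeric(0),
                                          grid_y = 1), "empty grid")
})

test_that("zero-boundary extraction matches analytic contours", {
  gx <- seq(0, 1, length.out = 51); gy <- seq(0, 1, length.out = 41)
  cval <- 0.4
  planar <- structure(list(x = gx, y = gy,
                           z = array(outer(gx - cval, rep(1, 41)),
                                     c(51, 41, 1),
                                     dimnames = list(NULL, NULL, "LV1"))),
                      class = "latent_surface")
  bs <- extract_zero_boundaries(planar, min_vertices = 2)
  expect_identical(unname(bs$notes), "ok")
  expect_length(bs$boundaries$LV1, 1)
  poly <- bs$boundaries$LV1[[1]]
  expect_true(all(abs(poly$x - cval) <= diff(gx[1:2]) + 1e-12))
  expect_gte(min(poly$y), 0); expect_lte(max(poly$y), 1)

  positive <- planar
  positive$z[] <- positive$z + 2
  bp <- extract_zero_boundaries(positive)
  expect_length(bp$boundaries$LV1, 0)
  expect_identical(unname(bp$notes), "no-sign-change")
})

test_that("contour count matches a sign-component scan on a two-bump field", {
  gx <- seq(-2, 2, length.out = 81); gy <- seq(-2, 2, length.out = 81)
  bump <- function(cx, cy) outer(gx, gy, function(x, y)
    exp(-((x - cx)^2 + (y - cy)^2) / 0.08))
  z <- bump(-1, -1) + bump(1, 1) - 0.5
  surf <- structure(list(x = gx, y = gy,
                         z = array(z, c(81, 81, 1),
                                   dimnames = list(NULL, NULL, "LV1"))),
                    class = "latent_surface")
  bs <- extract_zero_boundaries(surf, min_vertices = 3)
  # oracle: connected components of the positive region by flood fill
  pos <- z > 0
  comp <- matrix(0L, 81, 81); nc <- 0L
  for (s0 in which(pos & comp == 0)) {
    if (comp[s0] != 0) next
    nc <- nc + 1L
    queue <- s0
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]
      if (comp[q] != 0 || !pos[q]) next
      comp[q] <- nc
      i <- (q - 1) %% 81 + 1; j <- (q - 1) %/% 81 + 1
      nb <- c(if (i > 1) q - 1, if (i < 81) q + 1,
              if (j > 1) q - 81, if (j < 81) q + 81)
      queue <- c(queue, nb[pos[nb] & comp[nb] == 0])
    }
  }
  expect_equal(length(bs$boundaries$LV1), nc)
  expect_equal(nc, 2L)
})

test_that("broad near-zero fields are flagged instead of contoured", {
  gx <- seq(0, 1, length.out = 41); gy <- gx
  set.seed(3)
  z <- matrix(rnorm(41 * 41, sd = 1e-4), 41, 41)
  z[1, 1] <- 1; z[41, 41] <- -1          # sign change but almost-all-zero field
  surf <- structure(list(x = gx, y = gy,
                         z = array(z, c(41, 41, 1),
                                   dimnames = list(NULL, NULL, "LV3"))),
                    class = "latent_surface")
  bs <- extract_zero_boundaries(surf)
  expect_identical(unname(bs$notes), "broad-zero-area")
  expect_length(bs$boundaries$LV3, 0)
})
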