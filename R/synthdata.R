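#' Sites along a synthetic coastline
#'
#' Places `n` sites along a half-elliptic arc — a one-dimensional coastline
#' embedded in two dimensions — dividing the arc length near-evenly and
#' adding a small coordinate jitter. Coordinates are rescaled so that the
#' total arc length is 1; spatial ranges for synthetic fields are therefore
#' expressed as fractions of the coastline length.
#'
#' @param n number of sites (>= 2).
#' @param seed integer seed; output is deterministic given `seed`.
#' @param jitter_sd standard deviation of the coordinate jitter.
#' @return an n x 2 matrix with columns `x`, `y`.
#' @export
generate_coastline_sites <- function(n, seed = 1, jitter_sd = 0.002) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stopf("`n` must be a single integer >= 2")
  n <- as.integer(n)
  # half-ellipse, arc-length parameterized numerically
  a <- 1; b <- 0.5
  tt <- seq(0, pi, length.out = 4096L)
  px <- a * cos(tt); py <- b * sin(tt)
  seg <- sqrt(diff(px)^2 + diff(py)^2)
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  targets <- seq(0, total, length.out = n)
  t_at <- stats::approx(arc, tt, xout = targets, ties = "ordered")$y
  xy <- cbind(x = a * cos(t_at), y = b * sin(t_at)) / total
  withr_seed <- seed
  set.seed(withr_seed)
  xy <- xy + matrix(stats::rnorm(2L * n, sd = jitter_sd), ncol = 2L)
  colnames(xy) <- c("x", "y")
  rownames(xy) <- sprintf("site_%03d", seq_len(n))
  xy
}

#' Draw spatially autocorrelated latent fields
#'
#' Samples zero-mean Gaussian fields over the site set, one column per
#' latent dimension, with the module-standard Matern covariance
#' ([matern_covariance()]). A field with `sds[l] = 0` is identically zero.
#'
#' @param coords site coordinates (n x 2).
#' @param ranges vector of spatial ranges, one per field.
#' @param sds vector of marginal standard deviations (>= 0), one per field.
#' @param seed integer seed.
#' @param smoothness Matern smoothness.
#' @param distance distance convention.
#' @return an n x length(ranges) matrix of field values.
#' @export
sample_matern_fields <- function(coords, ranges, sds, seed = 1,
                                 smoothness = 1.5,
                                 distance = c("euclidean", "haversine-km")) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stopf("`coords` must be nonempty")
  if (length(ranges) != length(sds))
    stopf("`ranges` and `sds` must have equal length")
  if (any(ranges <= 0)) stopf("all ranges must be positive")
  if (any(sds < 0)) stopf("all sds must be non-negative")
  distance <- match.arg(distance)
  n <- nrow(coords)
  L <- length(ranges)
  U <- matrix(0, n, L)
  set.seed(seed)
  for (l in seq_len(L)) {
    z <- stats::rnorm(n)
    if (sds[l] > 0) {
      C <- matern_covariance(coords, ranges[l], sds[l], smoothness, distance)
      ch <- chol(C + diag(1e-10 * sds[l]^2, n))
      U[, l] <- drop(crossprod(ch, z))
    }
  }
  colnames(U) <- sprintf("LV%d", seq_len(L))
  rownames(U) <- rownames(coords)
  U
}

#' Smooth environmental covariates over a synthetic coastline
#'
#' Two standardized covariates emulating field-measured gradients: the first
#' is dominated by a latitudinal (second-coordinate) trend, the second by an
#' along-coast oscillation; both carry small site-level noise and are
#' standardized to mean 0 / sd 1.
#'
#' @param coords site coordinates (n x 2).
#' @param seed integer seed.
#' @return an n x 2 matrix with columns `temperature`, `salinity`.
#' @export
generate_covariates <- function(coords, seed = 1) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1L) stopf("`coords` must be nonempty")
  n <- nrow(coords)
  set.seed(seed)
  lat <- coords[, 2L]
  v1 <- lat + 0.1 * sd(lat) * stats::rnorm(n)
  v2 <- sin(3 * pi * coords[, 1L] / max(abs(coords[, 1L]))) +
    0.3 * stats::rnorm(n)
  X <- cbind(temperature = as.numeric(scale(v1)),
             salinity = as.numeric(scale(v2)))
  rownames(X) <- rownames(coords)
  X
}

#' Configuration for the synthetic community generator
#'
#' Bundles and validates the generator settings. Defaults emulate a
#' regional coastal survey: ~500 sites along a coastline, several hundred
#' species, three smooth latent niche axes with decreasing spatial ranges,
#' modest covariate effects, low baseline prevalence and site-level
#' detectability effects.
#'
#' @param n_sites number of sites (>= 2).
#' @param n_species number of species.
#' @param n_latent number of latent fields, 0-5.
#' @param matern_ranges spatial range per field (length `n_latent`), as a
#'   fraction of the unit coastline.
#' @param matern_sd marginal sd per field (recycled).
#' @param covariate_effect_sd sd of species covariate coefficients
#'   (mean 0).
#' @param intercept_mean,intercept_sd distribution of species intercepts.
#' @param site_effect_sd sd of site random effects.
#' @param loading_mean,loading_sd distribution of species loadings.
#' @param read_depth optional mean reads per occupied cell; if set, a
#'   read-count layer is generated.
#' @param smoothness Matern smoothness of the latent fields.
#' @param seed integer seed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 500, n_species = 519, n_latent = 3,
                             matern_ranges = c(0.6, 0.3, 0.15)[seq_len(n_latent)],
                             matern_sd = 1,
                             covariate_effect_sd = 0.5,
                             intercept_mean = -2, intercept_sd = 1,
                             site_effect_sd = 0.5,
                             loading_mean = 0, loading_sd = 1,
                             read_depth = NULL,
                             smoothness = 1.5,
                             seed = 1) {
  if (n_sites < 2) stopf("`n_sites` must be >= 2")
  if (n_species < 1) stopf("`n_species` must be >= 1")
  if (n_latent < 0 || n_latent > 5) stopf("`n_latent` must be in 0..5")
  if (n_latent > 0 && length(matern_ranges) != n_latent)
    stopf("`matern_ranges` must have length `n_latent`")
  sds <- rep_len(matern_sd, max(n_latent, 1L))[seq_len(n_latent)]
  if (any(sds < 0)) stopf("`matern_sd` must be non-negative")
  if (site_effect_sd < 0 || covariate_effect_sd < 0 ||
      intercept_sd < 0 || loading_sd < 0)
    stopf("all sd parameters must be non-negative")
  if (!is.null(read_depth) && read_depth <= 0)
    stopf("`read_depth` must be positive when set")
  structure(list(
    n_sites = as.integer(n_sites), n_species = as.integer(n_species),
    n_latent = as.integer(n_latent),
    matern_ranges = as.numeric(matern_ranges)[seq_len(n_latent)],
    matern_sd = sds,
    covariate_effect_sd = covariate_effect_sd,
    intercept_mean = intercept_mean, intercept_sd = intercept_sd,
    site_effect_sd = site_effect_sd,
    loading_mean = loading_mean, loading_sd = loading_sd,
    read_depth = read_depth, smoothness = smoothness,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Generate a synthetic coastal community with full ground truth
#'
#' Draws every model quantity from the configured distributions, computes
#' occurrence probabilities through the logistic linear predictor
#' \eqn{\mathrm{logit}(p_{ij}) = \beta_{j0} + x_i^\top \beta_j +
#' u_i^\top \gamma_j + \alpha_i}, and samples Bernoulli detections. When
#' `read_depth` is set, occupied cells also receive read counts from a
#' zero-truncated Poisson so the count layer binarizes back to the
#' detections exactly.
#'
#' @param config a [synthetic_config()].
#' @return an object of class `synthetic_truth`: a list with `coords`,
#'   `sites` (a [site_table()]), `X`, `U`, `beta0`, `B`, `Gamma`, `alpha`,
#'   `eta`, `p`, `detections` (presence-mode [detection_matrix()]),
#'   `counts` (count-mode detection matrix or `NULL`) and `config`.
#' @export
generate_communities <- function(config = synthetic_config()) {
  if (!inherits(config, "synthetic_config"))
    stopf("`config` must be a `synthetic_config` object")
  n <- config$n_sites; S <- config$n_species; L <- config$n_latent
  coords <- generate_coastline_sites(n, seed = config$seed)
  X <- generate_covariates(coords, seed = config$seed + 1L)
  U <- if (L > 0) {
    sample_matern_fields(coords, config$matern_ranges, config$matern_sd,
                         seed = config$seed + 2L,
                         smoothness = config$smoothness)
  } else {
    matrix(0, n, 0)
  }
  set.seed(config$seed + 3L)
  beta0 <- stats::rnorm(S, config$intercept_mean, config$intercept_sd)
  B <- matrix(stats::rnorm(2L * S, 0, config$covariate_effect_sd), 2L, S,
              dimnames = list(colnames(X), NULL))
  Gamma <- matrix(stats::rnorm(L * S, config$loading_mean, config$loading_sd),
                  L, S)
  alpha <- stats::rnorm(n, 0, config$site_effect_sd)
  eta <- matrix(beta0, n, S, byrow = TRUE) + X %*% B + alpha
  if (L > 0) eta <- eta + U %*% Gamma
  p <- stats::plogis(eta)
  y <- matrix(stats::rbinom(n * S, 1L, p), n, S)

  species <- sprintf("sp_%03d", seq_len(S))
  dimnames(eta) <- dimnames(p) <- dimnames(y) <- list(rownames(coords), species)
  det <- detection_matrix(t(y), mode = "presence")

  counts <- NULL
  if (!is.null(config$read_depth)) {
    lam <- config$read_depth
    occ <- which(y == 1L)
    cm <- matrix(0L, n, S, dimnames = dimnames(y))
    # zero-truncated Poisson: inverse-cdf draw conditioned on > 0
    u <- stats::runif(length(occ), stats::dpois(0, lam), 1)
    cm[occ] <- stats::qpois(u, lam)
    counts <- detection_matrix(t(cm), mode = "counts")
  }

  district <- cut_districts(n)
  sites <- site_table(data.frame(
    site = rownames(coords), lon = coords[, 1L], lat = coords[, 2L],
    district = as.character(district),
    temperature = X[, 1L], salinity = X[, 2L]
  ), distance = "euclidean", districts = sprintf("D%d", 1:8))

  structure(list(coords = coords, sites = sites, X = X, U = U,
                 beta0 = beta0, B = B, Gamma = Gamma, alpha = alpha,
                 eta = eta, p = p, detections = det, counts = counts,
                 config = config),
            class = "synthetic_truth")
}

cut_districts <- function(n) {
  as.character(cut(seq_len(n), breaks = 8, labels = sprintf("D%d", 1:8)))
}

#' Resample detections from recorded truth
#'
#' Draws a fresh Bernoulli detection matrix from the occurrence
#' probabilities stored in a [generate_communities()] truth object,
#' holding every parameter fixed — replicate observations of the same
#' community.
#'
#' @param truth a `synthetic_truth` object.
#' @param seed integer seed.
#' @return a presence-mode [detection_matrix()].
#' @export
resample_detections <- function(truth, seed = 1) {
  if (!inherits(truth, "synthetic_truth"))
    stopf("`truth` must be a synthetic_truth object")
  set.seed(seed)
  y <- matrix(stats::rbinom(length(truth$p), 1L, truth$p), nrow(truth$p),
              dimnames = dimnames(truth$p))
  detection_matrix(t(y), mode = "presence")
}
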