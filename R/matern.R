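#' Matern correlation at given distances
#'
#' Correlation form of the Matern kernel,
#' \eqn{r(d) = (2^{1-\nu}/\Gamma(\nu)) (\kappa d)^\nu K_\nu(\kappa d)} with
#' \eqn{\kappa = \sqrt{8\nu}/\rho}, so that the range \eqn{\rho} is the
#' distance at which correlation has dropped to roughly 0.14 regardless of
#' smoothness.
#'
#' @param d numeric vector/matrix of distances (non-negative).
#' @param range spatial range \eqn{\rho > 0}, in the units of `d`.
#' @param smoothness smoothness \eqn{\nu}; one of 0.5, 1, 1.5.
#' @return correlations with the same shape as `d`; exactly 1 at `d = 0`.
#' @export
matern_correlation <- function(d, range, smoothness = 1.5) {
  if (!is.numeric(range) || length(range) != 1L || range <= 0)
    stopf("`range` must be a single positive number")
  if (!smoothness %in% c(0.5, 1, 1.5))
    stopf("unsupported smoothness %s: supported values are 0.5, 1, 1.5",
          format(smoothness))
  kappa <- sqrt(8 * smoothness) / range
  out <- d
  pos <- d > 0
  kd <- kappa * d[pos]
  out[pos] <- (2^(1 - smoothness) / gamma(smoothness)) *
    kd^smoothness * besselK(kd, smoothness)
  out[!pos] <- 1
  out
}

#' Matern covariance matrix over a site set
#'
#' Dense Matern covariance \eqn{C(d) = \sigma^2 r(d)} (see
#' [matern_correlation()]) between all pairs of sites.
#'
#' @param coords site coordinate matrix (n x 2).
#' @param range spatial range \eqn{\rho > 0}.
#' @param sd marginal standard deviation \eqn{\sigma > 0}.
#' @param smoothness Matern smoothness \eqn{\nu \in \{0.5, 1, 1.5\}}.
#' @param distance distance convention, see [site_distances()].
#' @return symmetric positive semidefinite n x n covariance matrix with
#'   \eqn{\sigma^2} on the diagonal.
#' @export
matern_covariance <- function(coords, range, sd, smoothness = 1.5,
                              distance = c("euclidean", "haversine-km")) {
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stopf("`sd` must be a single positive number")
  d <- site_distances(coords, method = match.arg(distance))
  sd^2 * matern_correlation(d, range, smoothness)
}

#' Sparse GMRF precision approximating a Matern field
#'
#' Builds a sparse precision matrix by nearest-neighbour conditioning
#' (a Vecchia-type construction): sites are ordered along the first
#' coordinate, each site is conditioned on its `n_neighbors` nearest
#' predecessors under the Matern covariance, and the implied precision
#' \eqn{Q = (I-A)^\top D^{-1} (I-A)} is assembled. With full conditioning
#' (`n_neighbors = n - 1`) the inverse of `Q` equals the dense Matern
#' covariance exactly (up to numerical error).
#'
#' @inheritParams matern_covariance
#' @param n_neighbors number of conditioning neighbours `m`, `1 <= m < n`.
#' @return a sparse symmetric positive definite precision matrix
#'   (class `dsCMatrix`), rows/columns in the original site order.
#' @export
gmrf_precision <- function(coords, range, sd, smoothness = 1.5,
                           n_neighbors = 10,
                           distance = c("euclidean", "haversine-km")) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 1L) stopf("need at least one site")
  if (n == 1L)
    return(Matrix::sparseMatrix(i = 1L, j = 1L, x = 1 / sd^2, dims = c(1L, 1L),
                                symmetric = TRUE))
  if (n_neighbors >= n)
    stopf("`n_neighbors` must be smaller than the number of sites (%d)", n)
  if (n_neighbors < 1L) stopf("`n_neighbors` must be at least 1")
  distance <- match.arg(distance)

  ord <- order(coords[, 1L], coords[, 2L])
  C <- matern_covariance(coords[ord, , drop = FALSE], range, sd, smoothness,
                         distance)
  D <- site_distances(coords[ord, , drop = FALSE], method = distance)

  ii <- jj <- xx <- vector("list", n)
  dvec <- numeric(n)
  dvec[1L] <- C[1L, 1L]
  ii[[1L]] <- 1L; jj[[1L]] <- 1L; xx[[1L]] <- 1
  for (i in 2:n) {
    prev <- seq_len(i - 1L)
    nb <- prev[order(D[i, prev])][seq_len(min(n_neighbors, i - 1L))]
    a <- solve(C[nb, nb, drop = FALSE], C[nb, i])
    dvec[i] <- C[i, i] - sum(C[nb, i] * a)
    ii[[i]] <- rep.int(i, length(nb) + 1L)
    jj[[i]] <- c(i, nb)
    xx[[i]] <- c(1, -a)
  }
  IA <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                             dims = c(n, n))
  Q_ord <- Matrix::crossprod(IA / sqrt(dvec))
  inv <- order(ord)
  Q <- Q_ord[inv, inv, drop = FALSE]
  methods::as(Matrix::forceSymmetric(Q), "CsparseMatrix")
}

## profile GP log-likelihood of a single field over the range parameter,
## with an iid nugget for estimation noise in the field (fixed when the
## noise level is known, estimated otherwise); the total variance is
## profiled out analytically
profile_range_mle <- function(field, coords, smoothness, distance,
                              lower = NULL, upper = NULL, nugget = NULL) {
  n <- length(field)
  d <- site_distances(coords, method = distance)
  pos <- d[upper.tri(d)]
  if (is.null(lower)) lower <- max(min(pos[pos > 0]), 1e-6)
  # ranges beyond the site-set diameter are not identifiable from data on
  # a bounded domain; the profile is capped there by convention
  if (is.null(upper)) upper <- max(pos)
  neg_pll <- function(rho, w) {
    R <- (1 - w) * matern_correlation(d, rho, smoothness) + diag(w, n)
    ch <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    z <- backsolve(ch, field, transpose = TRUE)
    s2 <- sum(z^2) / n
    sum(log(diag(ch))) + n / 2 * log(s2)
  }
  if (!is.null(nugget)) {
    w <- min(max(nugget, 0), 0.9)
    opt <- stats::optimize(function(lr) neg_pll(exp(lr), w),
                           interval = log(c(lower, upper)))
    list(range = exp(opt$minimum), nugget = w)
  } else {
    opt <- stats::optim(c(log(sqrt(lower * upper)), qlogis(0.1)),
                        function(par) {
                          rho <- exp(par[1L])
                          if (rho < lower || rho > upper) return(1e10)
                          neg_pll(rho, plogis(par[2L]))
                        },
                        method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-6))
    list(range = exp(opt$par[1L]), nugget = plogis(opt$par[2L]))
  }
}
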