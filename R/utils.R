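#' @keywords internal
"_PACKAGE"

#' @importFrom stats plogis qlogis rnorm rpois runif rbinom optim optimize
#'   quantile median sd var aggregate lm coef dist kmeans qpois dnorm setNames
#' @importFrom utils read.delim write.table head
#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve forceSymmetric
#' @importFrom methods as
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Pairwise site distances
#'
#' Distances between site coordinates under the convention declared for the
#' data: plain Euclidean distance for synthetic coordinates, or great-circle
#' (haversine) kilometres for longitude/latitude in decimal degrees.
#'
#' @param coords numeric matrix with two columns (x/y or lon/lat).
#' @param coords2 optional second coordinate matrix; if supplied the result is
#'   the rectangular cross-distance matrix.
#' @param method `"euclidean"` or `"haversine-km"`.
#' @return a numeric distance matrix.
#' @export
site_distances <- function(coords, coords2 = NULL,
                           method = c("euclidean", "haversine-km")) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  if (!is.null(coords2)) coords2 <- as.matrix(coords2)
  if (method == "euclidean") {
    if (is.null(coords2)) {
      as.matrix(stats::dist(coords))
    } else {
      # |a - b|^2 = |a|^2 + |b|^2 - 2 a.b, guarded against tiny negatives
      cross <- tcrossprod(coords, coords2)
      d2 <- outer(rowSums(coords^2), rowSums(coords2^2), "+") - 2 * cross
      sqrt(pmax(d2, 0))
    }
  } else {
    b <- if (is.null(coords2)) coords else coords2
    geosphere::distm(coords, b, fun = geosphere::distHaversine) / 1000
  }
}

## numerically safe Bernoulli log-probabilities from the linear predictor
log_p_from_eta <- function(eta) plogis(eta, log.p = TRUE)
log_q_from_eta <- function(eta) plogis(-eta, log.p = TRUE)

## interquartile range under the linear-interpolation quantile convention
iqr_linear <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
  q[2L] - q[1L]
}
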