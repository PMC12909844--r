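#' Expected species richness of a site
#'
#' Sum of occurrence probabilities over species,
#' \eqn{E[\mathrm{richness}_i] = \sum_j p_{ij}}.
#'
#' @param p occurrence probabilities: a vector (one site) or a sites x
#'   species matrix.
#' @return scalar, or per-site vector for matrix input.
#' @export
expected_richness <- function(p) {
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  if (is.matrix(p)) rowSums(p) else sum(p)
}

## IQR of the loadings of a present-species subset; < 2 present species
## contribute 0 by convention
community_iqr <- function(gamma, present) {
  if (sum(present) < 2L) 0 else iqr_linear(gamma[present])
}

#' Monte-Carlo expected response diversity of one site
#'
#' Communities are sampled from the estimated occurrence probabilities
#' (presence of species j drawn Bernoulli(p_j), independently); for each
#' sampled community the interquartile range of the latent-variable
#' loadings \eqn{\gamma} of the present species is computed
#' (linear-interpolation quantiles; communities with fewer than two
#' species contribute 0), and the IQRs are averaged over replicates.
#'
#' @param p occurrence probabilities for one site (length S).
#' @param gamma loadings of one latent axis (length S).
#' @param n_rep number of sampled communities (default 100).
#' @param seed integer seed.
#' @return scalar expected response diversity (>= 0).
#' @export
expected_response_diversity <- function(p, gamma, n_rep = 100, seed = 1) {
  if (length(p) != length(gamma)) stopf("`p` and `gamma` lengths disagree")
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  if (n_rep < 1) stopf("`n_rep` must be >= 1")
  set.seed(seed)
  S <- length(p)
  draws <- matrix(runif(S * n_rep) < p, S, n_rep)
  mean(vapply(seq_len(n_rep), function(r) community_iqr(gamma, draws[, r]),
              0))
}

#' Exact expected response diversity (enumeration oracle)
#'
#' Exhaustively enumerates all \eqn{2^S} communities, weighting the IQR of
#' the present-species loadings by the community probability under
#' independent Bernoulli occurrences; conventions identical to
#' [expected_response_diversity()]. Limited to S <= 20.
#'
#' @inheritParams expected_response_diversity
#' @return exact expected response diversity.
#' @export
exact_response_diversity <- function(p, gamma) {
  S <- length(p)
  if (length(gamma) != S) stopf("`p` and `gamma` lengths disagree")
  if (S > 20) stopf("enumeration limited to 20 species (got %d)", S)
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  total <- 0
  for (mask in 0:(2^S - 1)) {
    present <- as.logical(bitwAnd(bitwShiftR(mask, 0:(S - 1L)), 1L))
    pr <- prod(ifelse(present, p, 1 - p))
    if (pr > 0 && sum(present) >= 2L)
      total <- total + pr * iqr_linear(gamma[present])
  }
  total
}

#' Expected response diversity for all sites and latent axes
#'
#' Convenience wrapper applying [expected_response_diversity()] to every
#' site and latent axis of a fitted model (or to explicit `p` and loading
#' inputs), with one deterministic seed stream.
#'
#' @param p sites x species occurrence probability matrix.
#' @param loadings L x species loading matrix (e.g. scaled loadings of a
#'   fit).
#' @param n_rep sampled communities per site.
#' @param seed integer seed.
#' @return sites x L matrix of expected response diversity.
#' @export
community_response_diversity <- function(p, loadings, n_rep = 100, seed = 1) {
  loadings <- as.matrix(loadings)
  if (ncol(p) != ncol(loadings)) stopf("species dimensions disagree")
  n <- nrow(p); L <- nrow(loadings)
  out <- matrix(NA_real_, n, L,
                dimnames = list(rownames(p), rownames(loadings)))
  for (i in seq_len(n)) {
    for (l in seq_len(L)) {
      out[i, l] <- expected_response_diversity(p[i, ], loadings[l, ],
                                               n_rep = n_rep,
                                               seed = seed + (i - 1L) * L + l)
    }
  }
  out
}

## normalized spectral embedding of 2-D points with an RBF affinity
spectral_embedding <- function(xy, sigma = NULL) {
  d <- as.matrix(dist(xy))
  if (is.null(sigma)) {
    pos <- d[upper.tri(d)]
    sigma <- median(pos[pos > 0])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  A <- exp(-d^2 / (2 * sigma^2))
  diag(A) <- 0
  dg <- rowSums(A)
  dg[dg == 0] <- 1e-12
  Lsym <- diag(nrow(A)) - sweep(sweep(A, 1, sqrt(dg), "/"), 2, sqrt(dg), "/")
  ev <- eigen(Lsym, symmetric = TRUE)
  V <- ev$vectors[, ncol(Lsym) - (0:1), drop = FALSE]  # two smallest
  nv <- sqrt(rowSums(V^2)); nv[nv == 0] <- 1
  V / nv
}

#' Cluster sites into high/low response diversity
#'
#' Spectral clustering (RBF affinity, normalized Laplacian, two clusters)
#' of the sites on the log-log plane of expected richness vs expected
#' response diversity. The k-means step is restarted `n_restarts` times;
#' each restart is scored by the summed Gaussian log-likelihood of the
#' residuals of per-cluster `log(rd) ~ log(richness)` regressions, and the
#' best-scoring restart is returned. The cluster with the larger mean
#' log response diversity is labelled `"high"`.
#'
#' @param richness per-site expected richness (> 0 required for use).
#' @param rd per-site expected response diversity for one latent axis.
#' @param n_restarts clustering restarts.
#' @param seed integer seed.
#' @return list with `labels` (factor `"high"`/`"low"` per site; `NA` for
#'   sites with non-positive richness or rd), `loglik` (score of the
#'   selected restart) and `restart` (its index).
#' @export
cluster_sites <- function(richness, rd, n_restarts = 100, seed = 1) {
  if (length(richness) != length(rd)) stopf("input lengths disagree")
  ok <- richness > 0 & rd > 0 & is.finite(richness) & is.finite(rd)
  if (sum(ok) < 4) stopf("need at least 4 sites with positive richness and rd")
  xy <- cbind(log(richness[ok]), log(rd[ok]))
  if (nrow(unique(xy)) < 2) stopf("need at least 2 distinct points")
  V <- spectral_embedding(xy)
  best <- NULL; best_ll <- -Inf; best_r <- NA_integer_
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    km <- tryCatch(stats::kmeans(V, centers = 2L, nstart = 1L),
                   error = function(e) NULL)
    if (is.null(km) || length(unique(km$cluster)) < 2L) next
    ll <- 0
    degenerate <- FALSE
    for (cl in 1:2) {
      sel <- km$cluster == cl
      if (sum(sel) < 3L) { degenerate <- TRUE; break }
      f <- lm(xy[sel, 2L] ~ xy[sel, 1L])
      res <- stats::residuals(f)
      s2 <- mean(res^2)
      if (s2 <= 0) s2 <- 1e-12
      ll <- ll + sum(dnorm(res, 0, sqrt(s2), log = TRUE))
    }
    if (degenerate) next
    if (ll > best_ll) { best_ll <- ll; best <- km$cluster; best_r <- r }
  }
  if (is.null(best)) stopf("no valid clustering found across restarts")
  m1 <- mean(xy[best == 1L, 2L]); m2 <- mean(xy[best == 2L, 2L])
  hi <- if (m1 >= m2) 1L else 2L
  lab <- rep(NA_character_, length(richness))
  lab[ok] <- ifelse(best == hi, "high", "low")
  list(labels = factor(lab, levels = c("high", "low")),
       loglik = best_ll, restart = best_r)
}

#' Per-cluster log-log richness regressions
#'
#' Ordinary least squares of `log(rd) ~ log(richness)` within each cluster
#' label; sites with non-positive richness or response diversity are
#' excluded and counted.
#'
#' @param richness per-site expected richness.
#' @param rd per-site expected response diversity.
#' @param labels cluster label per site (`NA` allowed).
#' @return data frame with one row per cluster: `cluster`, `n`,
#'   `n_excluded`, `slope`, `intercept`, `residual_sd`.
#' @export
fit_loglog_regression <- function(richness, rd, labels) {
  if (length(richness) != length(rd) || length(rd) != length(labels))
    stopf("input lengths disagree")
  labels <- as.factor(labels)
  rows <- lapply(levels(labels), function(cl) {
    in_cl <- !is.na(labels) & labels == cl
    usable <- in_cl & richness > 0 & rd > 0
    if (sum(usable) < 3)
      stopf("cluster '%s' has fewer than 3 usable sites", cl)
    f <- lm(log(rd[usable]) ~ log(richness[usable]))
    data.frame(cluster = cl, n = sum(usable),
               n_excluded = sum(in_cl) - sum(usable),
               slope = unname(coef(f)[2L]),
               intercept = unname(coef(f)[1L]),
               residual_sd = summary(f)$sigma,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
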