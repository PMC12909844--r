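#' Per-district richness summaries
#'
#' Groups per-site species richness by the declared district labels and
#' summarises each group (n, median, quartiles under the
#' linear-interpolation quantile convention).
#'
#' @param richness named numeric vector of per-site richness (names are
#'   site ids), as from [site_richness()].
#' @param sites a [site_table()].
#' @return data frame with one row per non-empty district: `district`, `n`,
#'   `q1`, `median`, `q3`.
#' @export
district_richness_summary <- function(richness, sites) {
  if (!all(names(richness) %in% sites$site))
    stopf("richness names and site table ids do not match")
  lab <- sites$district[match(names(richness), sites$site)]
  vocab <- attr(sites, "districts")
  if (!all(lab %in% vocab))
    stopf("unknown district label(s): %s",
          paste(setdiff(lab, vocab), collapse = ", "))
  groups <- split(unname(richness), lab)
  groups <- groups[lengths(groups) > 0]
  out <- data.frame(
    district = names(groups),
    n = lengths(groups),
    q1 = vapply(groups, function(v) quantile(v, 0.25, type = 7, names = FALSE), 0),
    median = vapply(groups, median, 0),
    q3 = vapply(groups, function(v) quantile(v, 0.75, type = 7, names = FALSE), 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$district), , drop = FALSE]
}

#' t-SNE embedding of a site distance matrix
#'
#' Nonlinear 2-D ordination of sites from a precomputed (e.g. Jaccard)
#' distance matrix, via exact t-SNE. Deterministic for a fixed seed.
#'
#' @param dist_matrix square symmetric distance matrix.
#' @param perplexity t-SNE perplexity; must satisfy `3 * perplexity < n - 1`.
#' @param seed integer seed.
#' @param max_iter gradient-descent iterations.
#' @return n x 2 matrix of embedding coordinates (rownames kept).
#' @export
tsne_embed <- function(dist_matrix, perplexity = 30, seed = 1,
                       max_iter = 500) {
  d <- as.matrix(dist_matrix)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stopf("`dist_matrix` must be square and symmetric")
  n <- nrow(d)
  if (perplexity >= n - 1) stopf("`perplexity` must be below n - 1")
  if (3 * perplexity >= n - 1)
    stopf("`perplexity` too large for %d sites (needs 3*perplexity < n-1)", n)
  set.seed(seed)
  fit <- Rtsne::Rtsne(d, is_distance = TRUE, dims = 2L,
                      perplexity = perplexity, theta = 0,
                      max_iter = max_iter, verbose = FALSE)
  out <- fit$Y
  rownames(out) <- rownames(d)
  colnames(out) <- c("dim1", "dim2")
  out
}
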