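# orthogonal Procrustes alignment of an estimated latent matrix to a
# reference; latent axes are identified only up to rotation and sign
procrustes_align <- function(U_hat, U_ref) {
  s <- svd(crossprod(U_hat, U_ref))
  U_hat %*% s$u %*% t(s$v)
}

# site_table for a subset of rows, keeping attributes
subset_sites <- function(sites, keep) {
  site_table(as.data.frame(sites)[keep, , drop = FALSE],
             distance = attr(sites, "distance"),
             districts = attr(sites, "districts"))
}

# even-odd rule point-in-polygon (polygon rows ordered, not closed)
sp_in_poly <- function(pt, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > pt[2]) != (yj > pt[2]) &&
        pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# small random count matrix for property tests
random_counts <- function(n_sp, n_si, lambda = 3) {
  matrix(stats::rpois(n_sp * n_si, lambda), n_sp, n_si,
         dimnames = list(sprintf("sp%d", seq_len(n_sp)),
                         sprintf("si%d", seq_len(n_si))))
}
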