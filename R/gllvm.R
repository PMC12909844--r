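#' Spatial prior settings for the latent fields
#'
#' @param smoothness Matern smoothness (0.5, 1 or 1.5).
#' @param ranges optional fixed/initial spatial range per latent dimension;
#'   when `NULL` a data-driven initial value (20% of the site-set diameter)
#'   is used.
#' @param n_neighbors neighbours for the sparse GMRF construction.
#' @param construction `"sparse-gmrf"` (nearest-neighbour conditioning) or
#'   `"dense"` (full covariance inverse; small problems only).
#' @return an object of class `spatial_prior`.
#' @export
spatial_prior <- function(smoothness = 1.5, ranges = NULL, n_neighbors = 10,
                          construction = c("sparse-gmrf", "dense")) {
  if (!smoothness %in% c(0.5, 1, 1.5))
    stopf("unsupported smoothness %s", format(smoothness))
  if (!is.null(ranges) && any(ranges <= 0)) stopf("ranges must be positive")
  structure(list(smoothness = smoothness, ranges = ranges,
                 n_neighbors = as.integer(n_neighbors),
                 construction = match.arg(construction)),
            class = "spatial_prior")
}

#' Candidate model specification
#'
#' A GLLVM candidate: which environmental covariates enter the linear
#' predictor, how many spatially autocorrelated latent variables, and
#' whether site random effects are included.
#'
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param n_latent number of latent variables, 0-5.
#' @param site_effects include site random effects \eqn{\alpha_i}?
#' @param label short identifier used in CV tables.
#' @param prior a [spatial_prior()].
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(covariates = character(0), n_latent = 2,
                       site_effects = TRUE, label = NULL,
                       prior = spatial_prior()) {
  if (n_latent < 0 || n_latent > 5) stopf("`n_latent` must be in 0..5")
  if (is.null(label))
    label <- sprintf("cov%d_L%d", length(covariates), n_latent)
  structure(list(covariates = as.character(covariates),
                 n_latent = as.integer(n_latent),
                 site_effects = isTRUE(site_effects),
                 label = label, prior = prior),
            class = "model_spec")
}

#' Enumerate the candidate model grid
#'
#' Crosses the named covariate sets with the latent-dimension range; with
#' three covariate sets and dimensions 0-5 this yields the standard grid of
#' 18 candidate models.
#'
#' @param covariate_sets named list of covariate-name vectors.
#' @param n_latent integer vector of latent dimensions to consider.
#' @param site_effects include site effects in every candidate?
#' @param prior shared [spatial_prior()].
#' @return list of [model_spec()] objects, labelled `"<set>_L<d>"`.
#' @export
candidate_model_grid <- function(covariate_sets, n_latent = 0:5,
                                 site_effects = TRUE,
                                 prior = spatial_prior()) {
  if (is.null(names(covariate_sets)) || any(names(covariate_sets) == ""))
    stopf("`covariate_sets` must be a named list")
  specs <- list()
  for (nm in names(covariate_sets)) {
    for (L in n_latent) {
      specs[[sprintf("%s_L%d", nm, L)]] <-
        model_spec(covariate_sets[[nm]], n_latent = L,
                   site_effects = site_effects,
                   label = sprintf("%s_L%d", nm, L), prior = prior)
    }
  }
  specs
}

#' Fitting options
#'
#' @param maxit maximum L-BFGS-B iterations per inner optimisation.
#' @param factr L-BFGS-B convergence tolerance factor.
#' @param n_outer outer iterations (inner fit + hyperparameter update).
#' @param estimate_ranges re-estimate each latent range by profile
#'   likelihood on the fitted field between outer iterations?
#' @param sigma_alpha_init initial site-effect standard deviation.
#' @param ridge Gaussian shrinkage precision on loadings and on intercept
#'   deviations from the prevalence logit, and the initial precision for
#'   covariate coefficients; the default 1 corresponds to standard-normal
#'   priors, natural for standardized covariates and unit-variance latent
#'   fields, and guards against quasi-separation. The per-covariate
#'   coefficient precision is re-estimated empirically between outer
#'   iterations.
#' @param init_sd standard deviation of the random initial values for
#'   latent fields and off-diagonal loadings.
#' @param seed integer seed controlling initialisation.
#' @return an object of class `gllvm_control`.
#' @export
gllvm_control <- function(maxit = 2000, factr = 1e10, n_outer = 3,
                          estimate_ranges = TRUE, sigma_alpha_init = 0.5,
                          ridge = 1, init_sd = 0.05, seed = 1) {
  structure(list(maxit = as.integer(maxit), factr = factr,
                 n_outer = as.integer(n_outer),
                 estimate_ranges = isTRUE(estimate_ranges),
                 sigma_alpha_init = sigma_alpha_init, ridge = ridge,
                 init_sd = init_sd, seed = as.integer(seed)),
            class = "gllvm_control")
}

#' Linear predictor and occurrence probabilities
#'
#' \eqn{\eta_{ij} = \beta_{j0} + x_i^\top \beta_j + u_i^\top \gamma_j +
#' \alpha_i} and \eqn{p_{ij} = 1/(1+e^{-\eta_{ij}})}, evaluated without
#' clamping via the numerically safe logistic.
#'
#' @param beta0 species intercepts (length S).
#' @param B covariate coefficient matrix (P x S); may have zero rows.
#' @param Gamma loading matrix (L x S); may have zero rows.
#' @param X covariate matrix (n x P).
#' @param U latent field matrix (n x L).
#' @param alpha site effects (length n, or a single 0).
#' @return list with matrices `eta` and `p` (n x S).
#' @export
linear_predictor <- function(beta0, B, Gamma, X, U, alpha = 0) {
  X <- as.matrix(X); U <- as.matrix(U)
  n <- max(nrow(X), nrow(U), length(alpha))
  S <- length(beta0)
  if (ncol(X) != nrow(B)) stopf("covariate dimensions disagree")
  if (ncol(U) != nrow(Gamma)) stopf("latent dimensions disagree")
  if (ncol(B) != S || ncol(Gamma) != S) stopf("species dimensions disagree")
  if (!length(alpha) %in% c(1L, n)) stopf("`alpha` length disagrees")
  eta <- matrix(beta0, n, S, byrow = TRUE) + alpha
  if (ncol(X) > 0) eta <- eta + X %*% B
  if (ncol(U) > 0) eta <- eta + U %*% Gamma
  list(eta = eta, p = stats::plogis(eta))
}

#' Bernoulli log-likelihood of a detection matrix
#'
#' \eqn{\sum_{ij} y_{ij} \log p_{ij} + (1-y_{ij}) \log(1-p_{ij})}. A cell
#' with \eqn{p \in \{0,1\}} contradicting its observation yields `-Inf`.
#'
#' @param p occurrence probability matrix, sites x species.
#' @param data a [detection_matrix()] (binarized) or a 0/1 matrix in the
#'   same sites x species orientation as `p`.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(p, data) {
  y <- if (inherits(data, "detection_matrix")) t(data$mat > 0) * 1 else data
  if (!all(dim(y) == dim(p))) stopf("`p` and `data` dimensions disagree")
  terms <- ifelse(y == 1, log(p), log1p(-p))
  sum(terms)
}

## stable per-cell negative log-likelihood from the linear predictor
nll_from_eta <- function(eta, y) {
  -(sum(y * log_p_from_eta(eta) + (1 - y) * log_q_from_eta(eta))) /
    length(y)
}

## ---- parameter packing for the penalized fit ------------------------------

gamma_free_count <- function(S, L) if (L == 0) 0L else sum(S - seq_len(L) + 1L)

build_gamma <- function(gfree, S, L) {
  G <- matrix(0, L, S)
  pos <- 1L
  for (l in seq_len(L)) {
    G[l, l] <- exp(gfree[pos]); pos <- pos + 1L
    if (l < S) {
      idx <- (l + 1L):S
      G[l, idx] <- gfree[pos + seq_along(idx) - 1L]
      pos <- pos + length(idx)
    }
  }
  G
}

grad_gamma_free <- function(dG, G, S, L) {
  out <- numeric(gamma_free_count(S, L))
  pos <- 1L
  for (l in seq_len(L)) {
    out[pos] <- dG[l, l] * G[l, l]; pos <- pos + 1L  # chain rule, log-diagonal
    if (l < S) {
      idx <- (l + 1L):S
      out[pos + seq_along(idx) - 1L] <- dG[l, idx]
      pos <- pos + length(idx)
    }
  }
  out
}

#' Fit a spatial Bernoulli GLLVM
#'
#' Maximizes a penalized Bernoulli log-likelihood over species intercepts,
#' covariate coefficients, constrained loadings, latent fields and site
#' effects: the latent fields carry a sparse GMRF (Matern) prior at unit
#' marginal variance (scale is absorbed by the loadings) and the site
#' effects a Gaussian prior. Optimisation is L-BFGS-B with analytic
#' gradients; between outer iterations each latent range is re-estimated by
#' profile Gaussian-process likelihood on the fitted field and the
#' site-effect variance by a Laplace EM-style update. The loading matrix
#' satisfies the standard GLLVM identifiability constraint exactly:
#' \eqn{\gamma_{lj} = 0} for species index \eqn{j < l} and
#' \eqn{\gamma_{ll} > 0}.
#'
#' @param detections a presence-mode (or binarized) [detection_matrix()].
#' @param sites a [site_table()] covering the same sites.
#' @param spec a [model_spec()].
#' @param control a [gllvm_control()].
#' @return an object of class `sgllvm_fit` with elements `beta0`, `B`,
#'   `Gamma`, `U`, `alpha`, `sigma_alpha`, `ranges`, `smoothness`,
#'   `objective` (final penalized log-likelihood), `trace` (accepted
#'   objective values, non-increasing in the negative direction),
#'   `convergence` (0 = converged), `eta`, `p`, plus the data bindings
#'   needed for prediction.
#' @export
fit_gllvm <- function(detections, sites, spec, control = gllvm_control()) {
  if (!inherits(detections, "detection_matrix"))
    stopf("`detections` must be a detection_matrix")
  if (!inherits(spec, "model_spec")) stopf("`spec` must be a model_spec")
  if (!setequal(colnames(detections$mat), sites$site))
    stopf("site ids of detections and site table do not match")
  sites <- sites[match(colnames(detections$mat), sites$site), , drop = FALSE]
  Y <- t(detections$mat > 0) * 1
  n <- nrow(Y); S <- ncol(Y)
  L <- spec$n_latent; P <- length(spec$covariates)
  coords <- site_coords(sites)
  distance <- attr(sites, "distance") %||% "euclidean"

  miss <- setdiff(spec$covariates, names(sites))
  if (length(miss) > 0)
    stopf("covariates absent from site table: %s", paste(miss, collapse = ", "))
  Xraw <- as.matrix(as.data.frame(sites)[, spec$covariates, drop = FALSE])
  if (anyNA(Xraw)) stopf("missing covariate values; filter sites first")
  x_center <- if (P > 0) colMeans(Xraw) else numeric(0)
  x_scale <- if (P > 0) apply(Xraw, 2, sd) else numeric(0)
  x_scale[x_scale == 0] <- 1
  X <- if (P > 0) scale(Xraw, x_center, x_scale) else matrix(0, n, 0)

  prev <- pmin(pmax(colMeans(Y), 0.5 / n), 1 - 0.5 / n)
  beta0_init <- qlogis(prev)

  ranges <- spec$prior$ranges
  dmax <- max(site_distances(coords, method = distance))
  if (is.null(ranges)) ranges <- rep(0.2 * dmax, L)
  if (length(ranges) != L && L > 0) ranges <- rep_len(ranges, L)
  smoothness <- spec$prior$smoothness
  m_nb <- min(spec$prior$n_neighbors, n - 1L)
  sa2 <- control$sigma_alpha_init^2
  use_alpha <- spec$site_effects
  lambda <- control$ridge
  # per-covariate shrinkage precision, re-estimated empirically between
  # outer iterations: a covariate that explains nothing collapses to a
  # high-precision (near-zero coefficient) prior
  lambda_B <- rep(lambda, P)

  ng <- gamma_free_count(S, L)
  set.seed(control$seed)
  # initial latent structure from an SVD of working logit-scale residuals,
  # rotated so the loading constraint holds at the starting point
  U0 <- matrix(rnorm(n * L, 0, control$init_sd), n, L)
  G0 <- matrix(rnorm(L * S, 0, control$init_sd), L, S)
  if (L > 0) {
    W <- prev * (1 - prev)
    Zres <- sweep(sweep(Y, 2, prev, "-"), 2, W, "/")
    Zres <- pmin(pmax(Zres, -8), 8)
    sv <- svd(Zres, nu = L, nv = L)
    scl <- apply(sv$u[, seq_len(L), drop = FALSE], 2, sd)
    U0 <- sweep(sv$u[, seq_len(L), drop = FALSE], 2, scl, "/")
    G0 <- diag(sv$d[seq_len(L)] * scl, L) %*%
      t(sv$v[, seq_len(L), drop = FALSE])
    rot <- constrain_loadings(U0, G0)
    U0 <- rot$U; G0 <- rot$G
    G0[cbind(seq_len(L), seq_len(L))] <-
      pmax(G0[cbind(seq_len(L), seq_len(L))], 0.05)
  }
  gfree0 <- numeric(ng)
  pos <- 1L
  for (l in seq_len(L)) {
    gfree0[pos] <- log(G0[l, l]); pos <- pos + 1L
    k <- S - l
    if (k > 0) {
      gfree0[pos + seq_len(k) - 1L] <- G0[l, (l + 1L):S]
      pos <- pos + k
    }
  }
  theta <- c(beta0_init, rep(0, P * S), gfree0, as.numeric(U0),
             if (use_alpha) rep(0, n))

  i_b0 <- seq_len(S)
  i_B <- if (P > 0) S + seq_len(P * S) else integer(0)
  i_g <- S + P * S + seq_len(ng)
  i_U <- S + P * S + ng + seq_len(n * L)
  i_a <- if (use_alpha) S + P * S + ng + n * L + seq_len(n) else integer(0)

  make_Q <- function(rng) {
    lapply(seq_len(L), function(l) {
      if (spec$prior$construction == "dense") {
        C <- matern_covariance(coords, rng[l], 1, smoothness, distance)
        methods::as(Matrix::forceSymmetric(solve(C + diag(1e-8, n))),
                    "CsparseMatrix")
      } else {
        gmrf_precision(coords, rng[l], 1, smoothness, m_nb, distance)
      }
    })
  }

  trace <- numeric(0)
  best <- Inf

  # each latent field enters the likelihood and penalty normalized to unit
  # root-mean-square: the scale direction (u -> cu, gamma -> gamma/c) is
  # otherwise unidentified in a penalized joint objective and would drift;
  # the loadings carry the scale, matching the scaled-latent reporting
  # convention
  unpack <- function(th) {
    V <- matrix(th[i_U], n, L)
    s <- if (L > 0) sqrt(colMeans(V^2)) else numeric(0)
    s[s < 1e-12] <- 1e-12
    list(beta0 = th[i_b0],
         B = matrix(th[i_B], P, S),
         G = build_gamma(th[i_g], S, L),
         V = V, u_scale = s,
         U = if (L > 0) sweep(V, 2, s, "/") else V,
         alpha = if (use_alpha) th[i_a] else rep(0, n))
  }

  obj_grad <- function(th, Qs, want_grad) {
    par <- unpack(th)
    eta <- matrix(par$beta0, n, S, byrow = TRUE) + par$alpha
    if (P > 0) eta <- eta + X %*% par$B
    if (L > 0) eta <- eta + par$U %*% par$G
    ll <- sum(Y * log_p_from_eta(eta) + (1 - Y) * log_q_from_eta(eta))
    pen <- 0
    if (L > 0) for (l in seq_len(L))
      pen <- pen + 0.5 * as.numeric(Matrix::crossprod(par$U[, l], Qs[[l]] %*% par$U[, l]))
    if (use_alpha) pen <- pen + 0.5 * sum(par$alpha^2) / sa2
    ridge <- 0.5 * lambda * (sum((par$beta0 - beta0_init)^2) + sum(par$G^2)) +
      0.5 * sum(lambda_B * rowSums(par$B^2))
    f <- -ll + pen + ridge
    if (!want_grad) return(f)
    Pm <- plogis(eta)
    R <- Y - Pm
    g <- numeric(length(th))
    g[i_b0] <- -colSums(R) + lambda * (par$beta0 - beta0_init)
    if (P > 0) g[i_B] <- as.numeric(-crossprod(X, R) + lambda_B * par$B)
    if (L > 0) {
      dG <- -crossprod(par$U, R) + lambda * par$G
      g[i_g] <- grad_gamma_free(dG, par$G, S, L)
      dU <- -(R %*% t(par$G))
      for (l in seq_len(L)) {
        gu <- dU[, l] + as.numeric(Qs[[l]] %*% par$U[, l])
        # chain rule through the unit-RMS normalization u = v / rms(v)
        dU[, l] <- (gu - par$U[, l] * mean(par$U[, l] * gu)) / par$u_scale[l]
      }
      g[i_U] <- as.numeric(dU)
    }
    if (use_alpha) g[i_a] <- -rowSums(R) + par$alpha / sa2
    list(f = f, g = g)
  }

  conv <- 0L
  for (outer in seq_len(control$n_outer)) {
    Qs <- if (L > 0) make_Q(ranges) else list()
    fn <- function(th) {
      f <- obj_grad(th, Qs, FALSE)
      if (f < best) { best <<- f; trace <<- c(trace, f) }
      f
    }
    gr <- function(th) obj_grad(th, Qs, TRUE)$g
    opt <- stats::optim(theta, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = control$maxit,
                                       factr = control$factr))
    theta <- opt$par
    conv <- max(conv, opt$convergence)
    par <- unpack(theta)
    if (outer < control$n_outer) {
      lp <- linear_predictor(par$beta0, par$B, par$G, X, par$U, par$alpha)
      Wm <- lp$p * (1 - lp$p)
      if (control$estimate_ranges && L > 0) {
        # the MAP field is a posterior mean, already smoothed by the GMRF
        # prior, so the profile uses a (numerically) zero nugget: a free
        # nugget on a smoothed field trades off against the range and
        # pushes the estimate to the domain-diameter cap
        for (l in seq_len(L)) {
          if (sd(par$U[, l]) > 1e-6)
            ranges[l] <- profile_range_mle(par$U[, l], coords, smoothness,
                                           distance, nugget = 1e-3)$range
        }
      }
      if (use_alpha) {
        W <- rowSums(Wm)
        sa2 <- mean(par$alpha^2 + 1 / (W + 1 / sa2))
        sa2 <- max(sa2, 1e-6)
      }
      if (P > 0) {
        # empirical-Bayes update of the per-covariate coefficient variance:
        # solve the EM fixed point for the prior precision, using the
        # unpenalized estimate implied by the current shrunk coefficients
        # (Laplace posterior-variance correction per species); a covariate
        # with no real effect collapses to a near-zero prior variance
        for (k in seq_len(P)) {
          Fk <- colSums(X[, k]^2 * Wm)
          B_ml <- par$B[k, ] * (Fk + lambda_B[k]) / Fk
          lam <- lambda_B[k]
          for (it in 1:50) {
            tau2 <- mean((Fk / (Fk + lam))^2 * B_ml^2 + 1 / (Fk + lam))
            lam_new <- min(1 / max(tau2, 1e-8), 1e6)
            if (abs(log(lam_new / lam)) < 1e-4) { lam <- lam_new; break }
            lam <- lam_new
          }
          lambda_B[k] <- lam
        }
      }
    }
  }
  if (conv != 0)
    warning("inner optimisation did not fully converge (optim code ",
            conv, ")", call. = FALSE)

  par <- unpack(theta)
  lp <- linear_predictor(par$beta0, par$B, par$G, X, par$U, par$alpha)
  dimnames(lp$p) <- dimnames(lp$eta) <- list(sites$site, rownames(detections$mat))
  # Laplace proxy for the estimation variance of each latent field value:
  # inverse of (Fisher information + marginal prior precision); used when
  # kriging to new sites
  krige_noise <- if (L > 0) {
    W <- lp$p * (1 - lp$p)
    1 / (W %*% t(par$G^2) + 1)
  } else {
    matrix(0, n, 0)
  }
  colnames(par$U) <- if (L > 0) sprintf("LV%d", seq_len(L)) else NULL
  rownames(par$U) <- sites$site

  structure(list(
    beta0 = setNames(par$beta0, rownames(detections$mat)),
    B = structure(par$B, dimnames = list(spec$covariates,
                                         rownames(detections$mat))),
    Gamma = structure(par$G, dimnames = list(colnames(par$U),
                                             rownames(detections$mat))),
    U = par$U, alpha = setNames(par$alpha, sites$site),
    krige_noise = krige_noise,
    sigma_alpha = sqrt(sa2), lambda_B = lambda_B,
    ranges = ranges, smoothness = smoothness,
    objective = -best, trace = -trace, convergence = conv,
    eta = lp$eta, p = lp$p,
    spec = spec, control = control,
    coords = coords, distance = distance,
    X = X, x_center = x_center, x_scale = x_scale,
    site_ids = sites$site, species_ids = rownames(detections$mat)
  ), class = "sgllvm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## rotate (U, Gamma) by an orthogonal map so that the leading L x L block
## of Gamma is upper triangular with non-negative diagonal; u' gamma is
## unchanged
constrain_loadings <- function(U, G) {
  L <- nrow(G)
  qr_ <- qr(G[, seq_len(L), drop = FALSE])
  Qm <- qr.Q(qr_)
  Gc <- crossprod(Qm, G)        # t(Q) %*% G has upper-triangular lead block
  Uc <- U %*% Qm
  flip <- sign(diag(Gc[, seq_len(L), drop = FALSE]))
  flip[flip == 0] <- 1
  Gc <- Gc * flip
  Uc <- sweep(Uc, 2, flip, "*")
  Gc[seq_len(L), seq_len(L)][lower.tri(matrix(0, L, L))] <- 0
  list(U = Uc, G = Gc)
}

#' @export
print.sgllvm_fit <- function(x, ...) {
  cat(sprintf("<sgllvm_fit> %d sites x %d species, %d latent variable(s)\n",
              length(x$site_ids), length(x$species_ids), x$spec$n_latent))
  if (x$spec$n_latent > 0)
    cat("  estimated ranges:", paste(signif(x$ranges, 3), collapse = ", "), "\n")
  cat(sprintf("  penalized log-likelihood: %.2f (convergence code %d)\n",
              x$objective, x$convergence))
  invisible(x)
}

#' Scaled latent fields and loadings
#'
#' Latent variables are reported scaled: each fitted field is divided by its
#' across-site standard deviation and the corresponding loadings multiplied
#' by it, a model-invariant rescaling of \eqn{u^\top \gamma}.
#'
#' @param fit an [fit_gllvm()] result.
#' @return list with `U` (scaled fields), `Gamma` (rescaled loadings) and
#'   `sd` (the per-axis scale factors).
#' @export
scaled_latents <- function(fit) {
  L <- fit$spec$n_latent
  if (L == 0) stopf("model has no latent variables")
  s <- apply(fit$U, 2, sd)
  s[s == 0] <- 1
  list(U = sweep(fit$U, 2, s, "/"), Gamma = fit$Gamma * s, sd = s)
}

#' Krige the latent fields to new locations
#'
#' Gaussian-process conditional mean and variance of each latent field at
#' new coordinates, conditioning on the fitted (posterior-mean) field
#' values under the fitted Matern correlation: the conditional mean is the
#' plain kriging interpolant of the fitted field (it reproduces the fitted
#' values at the training sites). With `uncertainty = "laplace"` the
#' returned variance adds the propagated estimation variance of the
#' training-site field values (Laplace/Fisher-information proxy recorded
#' at fit time) to the Gaussian-process conditional variance; with
#' `"none"` only the conditional variance is returned.
#'
#' @param fit an [fit_gllvm()] result with latent variables.
#' @param coords_new matrix of new coordinates (n_new x 2).
#' @param uncertainty `"laplace"` or `"none"`.
#' @return list with `mean` and `var` (each n_new x L); variances are of
#'   the unit-variance field.
#' @export
predict_latent <- function(fit, coords_new,
                           uncertainty = c("laplace", "none")) {
  uncertainty <- match.arg(uncertainty)
  L <- fit$spec$n_latent
  if (L == 0) stopf("model has no latent variables")
  coords_new <- as.matrix(coords_new)
  n <- nrow(fit$coords)
  d_tr <- site_distances(fit$coords, method = fit$distance)
  d_x <- site_distances(coords_new, fit$coords, method = fit$distance)
  mean_ <- var_ <- matrix(0, nrow(coords_new), L)
  for (l in seq_len(L)) {
    R <- matern_correlation(d_tr, fit$ranges[l], fit$smoothness) +
      diag(1e-8, n)
    cx <- matern_correlation(d_x, fit$ranges[l], fit$smoothness)
    w <- solve(R, t(cx))                  # kriging weights, one col per site
    mean_[, l] <- crossprod(w, fit$U[, l])
    var_[, l] <- pmax(1 - colSums(t(cx) * w), 0)
    if (uncertainty == "laplace")
      var_[, l] <- var_[, l] + colSums(w^2 * fit$krige_noise[, l])
  }
  colnames(mean_) <- colnames(var_) <- colnames(fit$U)
  list(mean = mean_, var = var_)
}

## scaling constant of the logistic-normal marginalization approximation
LOGIT_NORMAL_C2 <- (16 * sqrt(3) / (15 * pi))^2

## linear predictor mean and predictive variance at arbitrary sites;
## training sites (matched by id) reuse fitted latents and site effects
## with zero predictive variance
predict_parts <- function(fit, sites_new) {
  spec <- fit$spec
  P <- length(spec$covariates); L <- spec$n_latent
  miss <- setdiff(spec$covariates, names(sites_new))
  if (length(miss) > 0)
    stopf("covariates absent from new site table: %s",
          paste(miss, collapse = ", "))
  Xn_raw <- as.matrix(as.data.frame(sites_new)[, spec$covariates, drop = FALSE])
  if (anyNA(Xn_raw)) stopf("missing covariate values at prediction sites")
  Xn <- if (P > 0) scale(Xn_raw, fit$x_center, fit$x_scale) else
    matrix(0, nrow(sites_new), 0)
  nn <- nrow(sites_new)
  S <- length(fit$species_ids)
  idx <- match(sites_new$site, fit$site_ids)
  known <- !is.na(idx)

  U_new <- matrix(0, nn, L)
  alpha_new <- rep(0, nn)
  sig2 <- matrix(0, nn, S)
  if (any(known)) {
    if (L > 0) U_new[known, ] <- fit$U[idx[known], , drop = FALSE]
    alpha_new[known] <- fit$alpha[idx[known]]
  }
  if (any(!known)) {
    if (L > 0) {
      kr <- predict_latent(fit, site_coords(sites_new)[!known, , drop = FALSE])
      U_new[!known, ] <- kr$mean
      sig2[!known, ] <- kr$var %*% fit$Gamma^2
    }
    if (spec$site_effects)
      sig2[!known, ] <- sig2[!known, ] + fit$sigma_alpha^2
  }
  lp <- linear_predictor(fit$beta0, fit$B, fit$Gamma, Xn, U_new, alpha_new)
  dimnames(lp$eta) <- list(sites_new$site, fit$species_ids)
  list(eta = lp$eta, sig2 = sig2, known = known)
}

#' Predict occurrence probabilities at sites
#'
#' For sites present in the training set the fitted latent values and site
#' effects are reused, so training predictions reproduce the fitted
#' probabilities exactly. For new sites the latent fields are kriged
#' ([predict_latent()]), the site effect is set to its prior mean 0, and
#' the returned probability marginalizes the Gaussian predictive
#' uncertainty of the linear predictor through the standard
#' logistic-normal approximation
#' \eqn{p \approx \mathrm{logit}^{-1}(\eta/\sqrt{1 + c^2\sigma^2})}. Far
#' from all training sites the latent contribution shrinks to zero and the
#' prediction reduces to the covariate-only value.
#'
#' @param fit an [fit_gllvm()] result.
#' @param sites_new a [site_table()] (any mixture of training and new
#'   sites).
#' @param type `"response"` for (marginalized) probabilities, `"link"` for
#'   the mean linear predictor.
#' @return matrix (new sites x species).
#' @export
predict_occurrence <- function(fit, sites_new, type = c("response", "link")) {
  type <- match.arg(type)
  parts <- predict_parts(fit, sites_new)
  if (type == "link") return(parts$eta)
  stats::plogis(parts$eta / sqrt(1 + LOGIT_NORMAL_C2 * parts$sig2))
}

#' Variance partitioning of the linear predictor
#'
#' For each species, the across-site variance of every linear-predictor
#' component (one per covariate column, one per latent variable) is
#' computed and normalized to fractions summing to one; fractions are then
#' averaged over species with equal weights. Intercepts and site effects
#' are excluded from the partition.
#'
#' @param fit an [fit_gllvm()] result.
#' @return list with `fractions` (named average fractions summing to 1),
#'   `per_species` (component x species matrix of fractions) and
#'   `n_excluded` (species whose components all have zero variance).
#' @export
variance_partition <- function(fit) {
  P <- length(fit$spec$covariates); L <- fit$spec$n_latent
  if (P + L == 0) stopf("model has no covariates or latent variables to partition")
  comp_names <- c(fit$spec$covariates,
                  if (L > 0) sprintf("LV%d", seq_len(L)))
  S <- length(fit$species_ids)
  V <- matrix(0, P + L, S, dimnames = list(comp_names, fit$species_ids))
  for (k in seq_len(P))
    V[k, ] <- apply(fit$X[, k] %o% fit$B[k, ], 2, var)
  for (l in seq_len(L))
    V[P + l, ] <- apply(fit$U[, l] %o% fit$Gamma[l, ], 2, var)
  tot <- colSums(V)
  ok <- tot > 0
  if (!any(ok)) stopf("all linear-predictor components have zero variance")
  frac <- sweep(V[, ok, drop = FALSE], 2, tot[ok], "/")
  list(fractions = rowMeans(frac),
       per_species = frac,
       n_excluded = sum(!ok))
}

#' Cross-validated model selection
#'
#' Site-level k-fold cross validation over a list of candidate models:
#' folds are a random partition of the sites (shared across candidates);
#' each candidate is fitted on k-1 folds and scored by the mean per-cell
#' negative log-likelihood of the held-out sites under
#' [predict_occurrence()] (kriged latents, zero site effects). The
#' candidate with minimal mean validation loss is selected.
#'
#' @param detections a [detection_matrix()].
#' @param sites a [site_table()].
#' @param specs list of [model_spec()] objects.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param control a [gllvm_control()] shared by all fits.
#' @return object of class `sgllvm_cv`: list with `table` (one row per
#'   candidate: label, n_latent, mean and per-fold validation NLL),
#'   `folds` (fold id per site), `selected` (index of the best candidate)
#'   and `specs`.
#' @export
cross_validate_select <- function(detections, sites, specs, k = 5, seed = 1,
                                  control = gllvm_control()) {
  if (k < 2) stopf("`k` must be >= 2")
  if (length(specs) == 0) stopf("`specs` must be nonempty")
  sites <- sites[match(colnames(detections$mat), sites$site), , drop = FALSE]
  n <- nrow(sites)
  if (n < k) stopf("need at least k sites")
  set.seed(seed)
  fold <- sample(rep_len(seq_len(k), n))
  Y <- t(detections$mat > 0) * 1

  fold_nll <- matrix(NA_real_, length(specs), k)
  for (s in seq_along(specs)) {
    for (f in seq_len(k)) {
      tr <- fold != f
      det_tr <- detection_matrix(detections$mat[, tr, drop = FALSE],
                                 mode = detections$mode,
                                 is_species_complex = detections$is_species_complex)
      sites_tr <- site_table(sites[tr, , drop = FALSE],
                             distance = attr(sites, "distance"),
                             districts = attr(sites, "districts"))
      fit <- fit_gllvm(det_tr, sites_tr, specs[[s]], control)
      sites_te <- site_table(sites[!tr, , drop = FALSE],
                             distance = attr(sites, "distance"),
                             districts = attr(sites, "districts"))
      parts <- predict_parts(fit, sites_te)
      eta_adj <- parts$eta / sqrt(1 + LOGIT_NORMAL_C2 * parts$sig2)
      fold_nll[s, f] <- nll_from_eta(eta_adj, Y[!tr, , drop = FALSE])
    }
  }
  mean_nll <- rowMeans(fold_nll)
  labels <- vapply(specs, `[[`, "", "label")
  tab <- data.frame(label = labels,
                    n_latent = vapply(specs, `[[`, 0L, "n_latent"),
                    n_covariates = vapply(specs, function(x) length(x$covariates), 0L),
                    mean_nll = mean_nll, stringsAsFactors = FALSE)
  tab <- cbind(tab, structure(as.data.frame(fold_nll),
                              names = sprintf("fold%d", seq_len(k))))
  structure(list(table = tab, folds = setNames(fold, sites$site),
                 selected = which.min(mean_nll), specs = specs),
            class = "sgllvm_cv")
}

#' @export
print.sgllvm_cv <- function(x, ...) {
  cat(sprintf("<sgllvm_cv> %d candidate model(s), %d folds\n",
              nrow(x$table), sum(grepl("^fold", names(x$table)))))
  best <- x$table[x$selected, ]
  cat(sprintf("  selected: %s (mean validation NLL %.4f)\n",
              best$label, best$mean_nll))
  invisible(x)
}
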