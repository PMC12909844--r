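# shared small synthetic community for the fitting tests
make_small_truth <- function(seed = 31, n = 120, S = 40) {
  generate_communities(synthetic_config(
    n_sites = n, n_species = S, n_latent = 2, matern_ranges = c(0.3, 0.6),
    matern_sd = 1, covariate_effect_sd = 0.5, seed = seed))
}

test_that("linear predictor assembles the model equation", {
  # beta0 + x*beta + u*gamma + alpha = 0.5 - 0.5 + 0.5 - 0.5 = 0 -> p = 1/2
  lp <- linear_predictor(beta0 = 0.5,
                         B = matrix(-0.25, 1, 1),
                         Gamma = matrix(0.5, 1, 1),
                         X = matrix(2, 1, 1),
                         U = matrix(1, 1, 1), alpha = -0.5)
  expect_equal(lp$eta[1, 1], 0)
  expect_equal(lp$p[1, 1], 0.5)

  # all terms zero gives p = 1/2 as well
  lp0 <- linear_predictor(0, matrix(0, 0, 1), matrix(0, 0, 1),
                          matrix(0, 3, 0), matrix(0, 3, 0))
  expect_equal(unname(lp0$p), matrix(0.5, 3, 1))

  # p is strictly increasing in eta
  etas <- seq(-5, 5, by = 0.5)
  ps <- vapply(etas, function(e)
    linear_predictor(e, matrix(0, 0, 1), matrix(0, 0, 1),
                     matrix(0, 1, 0), matrix(0, 1, 0))$p[1, 1], 0)
  expect_true(all(diff(ps) > 0))

  expect_error(linear_predictor(c(0, 0), matrix(0, 1, 1), matrix(0, 0, 2),
                                matrix(0, 2, 2), matrix(0, 2, 0)),
               "disagree")
})

test_that("log-likelihood matches cell-wise Bernoulli arithmetic", {
  expect_equal(log_likelihood(matrix(0.5), matrix(1)), log(0.5))
  expect_equal(log_likelihood(matrix(1), matrix(1)), 0)
  expect_identical(log_likelihood(matrix(1), matrix(0)), -Inf)

  set.seed(7)
  p <- matrix(runif(9, 0.05, 0.95), 3, 3)
  y <- matrix(rbinom(9, 1, 0.5), 3, 3)
  brute <- 0
  for (i in 1:3) for (j in 1:3)
    brute <- brute + y[i, j] * log(p[i, j]) + (1 - y[i, j]) * log(1 - p[i, j])
  expect_equal(log_likelihood(p, y), brute, tolerance = 1e-12)
})

test_that("intercept-only fit reproduces the closed-form Bernoulli MLE", {
  tr <- make_small_truth(seed = 41, n = 60, S = 15)
  spec <- model_spec(character(0), n_latent = 0, site_effects = FALSE)
  fit <- fit_gllvm(tr$detections, tr$sites, spec, gllvm_control(seed = 1))
  prevalence <- colMeans(t(tr$detections$mat > 0) * 1)
  expect_equal(unname(fit$beta0), unname(qlogis(prevalence)),
               tolerance = 1e-4)
})

test_that("loading constraint holds exactly and the objective trace is monotone", {
  tr <- make_small_truth(seed = 51, n = 60, S = 20)
  fit <- suppressWarnings(fit_gllvm(
    tr$detections, tr$sites,
    model_spec(c("temperature", "salinity"), n_latent = 2),
    gllvm_control(seed = 1, maxit = 300)))
  expect_identical(fit$Gamma[2, 1], 0)
  expect_true(all(diag(fit$Gamma[, 1:2]) > 0))
  # recorded (accepted) objective values never decrease
  expect_true(all(diff(fit$trace) >= -1e-6))
  expect_true(all(is.finite(unlist(fit[c("beta0", "B", "Gamma", "U", "alpha")]))))
})

test_that("latent fields and probabilities are recovered on synthetic data", {
  tr <- make_small_truth(seed = 61)
  fit <- fit_gllvm(tr$detections, tr$sites,
                   model_spec(c("temperature", "salinity"), n_latent = 2),
                   gllvm_control(seed = 1))
  aligned <- procrustes_align(fit$U, tr$U)
  cors <- diag(cor(aligned, tr$U))
  expect_true(all(cors > 0.75))
  expect_lt(sqrt(mean((fit$p - tr$p)^2)), 0.15)
  # deterministic given identical options
  fit2 <- fit_gllvm(tr$detections, tr$sites,
                    model_spec(c("temperature", "salinity"), n_latent = 2),
                    gllvm_control(seed = 1))
  expect_identical(fit$U, fit2$U)
})

test_that("prediction reproduces training sites and shrinks far away", {
  tr <- make_small_truth(seed = 71, n = 80, S = 25)
  fit <- suppressWarnings(fit_gllvm(
    tr$detections, tr$sites,
    model_spec(c("temperature", "salinity"), n_latent = 2),
    gllvm_control(seed = 1, maxit = 500)))

  p_tr <- predict_occurrence(fit, tr$sites)
  expect_lt(max(abs(p_tr - fit$p)), 1e-8)

  far <- site_table(data.frame(site = "far", lon = 50, lat = 50,
                               district = "D1", temperature = 0.2,
                               salinity = -0.1),
                    distance = "euclidean", districts = "D1")
  eta_far <- predict_occurrence(fit, far, type = "link")
  Xf <- scale(matrix(c(0.2, -0.1), 1, 2), fit$x_center, fit$x_scale)
  eta_cov_only <- fit$beta0 + drop(Xf %*% fit$B)
  expect_equal(unname(drop(eta_far)), unname(eta_cov_only), tolerance = 1e-6)

  bad <- far
  bad$temperature <- NA
  expect_error(predict_occurrence(fit, bad), "missing covariate")
})

test_that("kriged latents equal the dense gaussian conditional", {
  tr <- make_small_truth(seed = 81, n = 40, S = 15)
  fit <- suppressWarnings(fit_gllvm(
    tr$detections, tr$sites,
    model_spec(c("temperature", "salinity"), n_latent = 2),
    gllvm_control(seed = 1, maxit = 400)))
  new_xy <- cbind(runif(5, min(fit$coords[, 1]), max(fit$coords[, 1])),
                  runif(5, min(fit$coords[, 2]), max(fit$coords[, 2])))
  kr <- predict_latent(fit, new_xy, uncertainty = "none")
  for (l in 1:2) {
    R <- matern_correlation(site_distances(fit$coords), fit$ranges[l], 1.5) +
      diag(1e-8, 40)
    cx <- matern_correlation(site_distances(new_xy, fit$coords),
                             fit$ranges[l], 1.5)
    expect_equal(kr$mean[, l], drop(cx %*% solve(R, fit$U[, l])),
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(kr$var[, l],
                 pmax(1 - diag(cx %*% solve(R, t(cx))), 0),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("variance partition normalizes per species and averages", {
  tr <- make_small_truth(seed = 91, n = 60, S = 20)
  # one latent variable and no covariates: the single component takes all
  fit1 <- suppressWarnings(fit_gllvm(
    tr$detections, tr$sites, model_spec(character(0), n_latent = 1),
    gllvm_control(seed = 1, maxit = 300)))
  vp1 <- variance_partition(fit1)
  expect_equal(unname(vp1$fractions), 1)

  fit2 <- suppressWarnings(fit_gllvm(
    tr$detections, tr$sites,
    model_spec(c("temperature", "salinity"), n_latent = 2),
    gllvm_control(seed = 1, maxit = 300)))
  vp2 <- variance_partition(fit2)
  expect_equal(sum(vp2$fractions), 1, tolerance = 1e-10)
  expect_true(all(colSums(vp2$per_species) - 1 < 1e-10))
  expect_named(vp2$fractions, c("temperature", "salinity", "LV1", "LV2"))
})

test_that("covariate fractions vanish when covariate effects are absent", {
  # truth built directly from the model equation with zero covariate
  # coefficients; covariates are non-spatial noise so they cannot proxy
  # the smooth latent fields by collinearity
  set.seed(9)
  n <- 250; S <- 40
  xy <- generate_coastline_sites(n, seed = 9)
  U <- sample_matern_fields(xy, c(0.3, 0.6), c(1, 1), seed = 10)
  Gam <- matrix(rnorm(2 * S), 2, S)
  beta0 <- rnorm(S, -1.5, 1)
  alpha <- rnorm(n, 0, 0.5)
  eta <- matrix(beta0, n, S, byrow = TRUE) + U %*% Gam + alpha
  y <- matrix(rbinom(n * S, 1, plogis(eta)), n, S,
              dimnames = list(rownames(xy), sprintf("sp%02d", 1:S)))
  Xn <- matrix(rnorm(2 * n), n, 2)
  sites <- site_table(data.frame(
    site = rownames(xy), lon = xy[, 1], lat = xy[, 2], district = "D1",
    temperature = Xn[, 1], salinity = Xn[, 2]
  ), distance = "euclidean", districts = "D1")
  fit <- suppressWarnings(fit_gllvm(
    detection_matrix(t(y)), sites,
    model_spec(c("temperature", "salinity"), n_latent = 2),
    gllvm_control(seed = 1)))
  vp <- variance_partition(fit)
  expect_lt(sum(vp$fractions[c("temperature", "salinity")]), 0.05)
})

test_that("cross-validation folds partition the sites and share across specs", {
  tr <- make_small_truth(seed = 111, n = 50, S = 12)
  specs <- list(model_spec(character(0), 0, label = "null"),
                model_spec(c("temperature"), 0, label = "temp"))
  cv <- suppressWarnings(cross_validate_select(
    tr$detections, tr$sites, specs, k = 5, seed = 3,
    control = gllvm_control(seed = 1, maxit = 200, n_outer = 1)))
  expect_length(cv$folds, 50)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_true(all(table(cv$folds) == 10))
  expect_equal(cv$selected, which.min(cv$table$mean_nll))
  expect_error(cross_validate_select(tr$detections, tr$sites, specs, k = 1),
               ">= 2")
})

test_that("the candidate grid crosses covariate sets with latent dimensions", {
  sets <- list(a = c("temperature", "salinity"),
               b = sprintf("sat%d", 1:4),
               c = c("temperature", "salinity", sprintf("sat%d", 1:4)))
  grid <- candidate_model_grid(sets, n_latent = 0:5)
  expect_length(grid, 18)
  expect_identical(names(grid)[1], "a_L0")
  expect_identical(grid[["c_L5"]]$n_latent, 5L)
  expect_identical(grid[["b_L3"]]$covariates, sets$b)
})

test_that("scaled latents have unit sd and preserve the latent term", {
  tr <- make_small_truth(seed = 121, n = 60, S = 20)
  fit <- suppressWarnings(fit_gllvm(
    tr$detections, tr$sites,
    model_spec(c("temperature", "salinity"), n_latent = 2),
    gllvm_control(seed = 1, maxit = 300)))
  sc <- scaled_latents(fit)
  expect_equal(unname(apply(sc$U, 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_equal(sc$U %*% sc$Gamma, fit$U %*% fit$Gamma, tolerance = 1e-10)
})
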