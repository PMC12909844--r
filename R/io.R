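#' Read / write a site table as CSV
#'
#' @param path file path.
#' @param distance distance convention of the coordinates.
#' @param districts optional district vocabulary.
#' @return a [site_table()].
#' @export
read_site_table <- function(path, distance = c("haversine-km", "euclidean"),
                            districts = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  site_table(df, distance = match.arg(distance), districts = districts)
}

#' @rdname read_site_table
#' @param sites a [site_table()].
#' @export
write_site_table <- function(sites, path) {
  utils::write.csv(as.data.frame(sites), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes all estimated parameters, the model specification and the
#' fitting options; [read_fit_json()] restores an `sgllvm_fit` usable for
#' prediction and downstream analysis.
#'
#' @param fit an [fit_gllvm()] result.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    beta0 = fit$beta0, B = fit$B, Gamma = fit$Gamma, U = fit$U,
    krige_noise = fit$krige_noise,
    alpha = fit$alpha, sigma_alpha = fit$sigma_alpha,
    ranges = fit$ranges, smoothness = fit$smoothness,
    objective = fit$objective, convergence = fit$convergence,
    spec = list(covariates = fit$spec$covariates,
                n_latent = fit$spec$n_latent,
                site_effects = fit$spec$site_effects,
                label = fit$spec$label,
                prior = unclass(fit$spec$prior)),
    control = unclass(fit$control),
    coords = fit$coords, distance = fit$distance,
    X = as.matrix(fit$X), x_center = fit$x_center, x_scale = fit$x_scale,
    site_ids = fit$site_ids, species_ids = fit$species_ids
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- model_spec(covariates = as.character(unlist(x$spec$covariates)),
                   n_latent = x$spec$n_latent,
                   site_effects = x$spec$site_effects,
                   label = x$spec$label,
                   prior = spatial_prior(
                     smoothness = x$spec$prior$smoothness,
                     ranges = unlist(x$spec$prior$ranges),
                     n_neighbors = x$spec$prior$n_neighbors,
                     construction = x$spec$prior$construction))
  P <- length(sp$covariates); L <- sp$n_latent
  S <- length(x$species_ids); n <- length(x$site_ids)
  shape <- function(m, nr, nc) {
    m <- matrix(as.numeric(m), nr, nc)
    m
  }
  U <- shape(x$U, n, L)
  colnames(U) <- if (L > 0) sprintf("LV%d", seq_len(L))
  rownames(U) <- x$site_ids
  structure(list(
    beta0 = setNames(as.numeric(x$beta0), x$species_ids),
    B = structure(shape(x$B, P, S), dimnames = list(sp$covariates, x$species_ids)),
    Gamma = structure(shape(x$Gamma, L, S),
                      dimnames = list(colnames(U), x$species_ids)),
    U = U,
    krige_noise = shape(x$krige_noise, n, L),
    alpha = setNames(as.numeric(x$alpha), x$site_ids),
    sigma_alpha = x$sigma_alpha,
    ranges = as.numeric(unlist(x$ranges)), smoothness = x$smoothness,
    objective = x$objective, trace = numeric(0),
    convergence = x$convergence,
    eta = NULL, p = NULL,
    spec = sp, control = do.call(gllvm_control, x$control[
      intersect(names(x$control), names(formals(gllvm_control)))]),
    coords = shape(x$coords, n, 2), distance = x$distance,
    X = shape(x$X, n, P),
    x_center = as.numeric(unlist(x$x_center)),
    x_scale = as.numeric(unlist(x$x_scale)),
    site_ids = x$site_ids, species_ids = x$species_ids
  ), class = "sgllvm_fit")
}

#' Export boundary polylines as GeoJSON
#'
#' One `LineString` feature per polyline, with the latent-variable name as
#' a property.
#'
#' @param boundaries a [extract_zero_boundaries()] result.
#' @param path output path.
#' @export
write_boundaries_geojson <- function(boundaries, path) {
  features <- list()
  for (nm in names(boundaries$boundaries)) {
    for (poly in boundaries$boundaries[[nm]]) {
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        properties = list(latent_variable = nm),
        geometry = list(type = "LineString",
                        coordinates = unname(as.matrix(poly)))
      )
    }
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
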