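#' Species-by-site detection matrix
#'
#' Container for a species x site table of eDNA detections, either raw read
#' counts or binary presence. Species and site identifiers must be unique;
#' count cells must be non-negative and presence cells in {0, 1}. When
#' `mode` is omitted it is inferred: an all-{0,1} table is presence,
#' anything else counts.
#'
#' @param mat numeric matrix, species in rows, sites in columns, with
#'   dimnames.
#' @param mode `"counts"` or `"presence"`; inferred when `NULL`.
#' @param is_species_complex logical vector flagging species that are
#'   unresolved complexes of several species (default none).
#' @return an object of class `detection_matrix`.
#' @export
detection_matrix <- function(mat, mode = NULL, is_species_complex = NULL) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("sp_%03d", seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("site_%03d", seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat)))
    stopf("duplicated species ids in detection table")
  if (anyDuplicated(colnames(mat)))
    stopf("duplicated site ids in detection table")
  if (!is.numeric(mat) || anyNA(mat) || any(mat < 0))
    stopf("detection cells must be non-negative numbers")
  binary <- all(mat %in% c(0, 1))
  if (is.null(mode)) mode <- if (binary) "presence" else "counts"
  mode <- match.arg(mode, c("counts", "presence"))
  if (mode == "presence" && !binary)
    stopf("presence-mode cells must all be 0 or 1")
  if (is.null(is_species_complex))
    is_species_complex <- rep(FALSE, nrow(mat))
  if (length(is_species_complex) != nrow(mat))
    stopf("`is_species_complex` must have one entry per species")
  structure(list(mat = mat, mode = mode,
                 is_species_complex = as.logical(is_species_complex)),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf("<detection_matrix> %d species x %d sites (%s mode", nrow(x$mat),
              ncol(x$mat), x$mode))
  nc <- sum(x$is_species_complex)
  if (nc > 0) cat(sprintf(", %d species-complex flags", nc))
  cat(")\n")
  invisible(x)
}

#' @export
dim.detection_matrix <- function(x) dim(x$mat)

#' Site metadata table
#'
#' A data frame of sites with coordinates, a district label and
#' environmental covariates (possibly missing), plus a declared distance
#' convention: Euclidean for synthetic coordinates, haversine kilometres for
#' longitude/latitude.
#'
#' @param df data frame with at least columns `site`, `lon`, `lat`,
#'   `district`; remaining columns are treated as covariates.
#' @param distance `"euclidean"` or `"haversine-km"`.
#' @param districts the allowed district vocabulary; defaults to the labels
#'   present.
#' @return the data frame with class `site_table` and attributes
#'   `distance`, `districts`.
#' @export
site_table <- function(df, distance = c("haversine-km", "euclidean"),
                       districts = NULL) {
  distance <- match.arg(distance)
  need <- c("site", "lon", "lat", "district")
  if (!all(need %in% names(df)))
    stopf("site table needs columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$site)) stopf("duplicated site ids in site table")
  if (!all(is.finite(df$lon)) || !all(is.finite(df$lat)))
    stopf("site coordinates must be finite")
  if (is.null(districts)) districts <- sort(unique(as.character(df$district)))
  if (!all(df$district %in% districts))
    stopf("district labels outside the declared vocabulary: %s",
          paste(setdiff(df$district, districts), collapse = ", "))
  structure(as.data.frame(df), class = c("site_table", "data.frame"),
            distance = distance, districts = districts)
}

site_coords <- function(sites) {
  as.matrix(sites[, c("lon", "lat")])
}

covariate_names <- function(sites) {
  setdiff(names(sites), c("site", "lon", "lat", "district"))
}

#' Read a detection table from TSV
#'
#' Expects a rectangular tab-separated table: header row of site ids, first
#' column of species ids, numeric cells.
#'
#' @param path file path.
#' @param is_species_complex optional species-complex flags (named by
#'   species id, or in row order).
#' @return a [detection_matrix()]; mode is inferred from the cells.
#' @export
read_detection_table <- function(path, is_species_complex = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("detection table needs species ids plus >= 1 site")
  sp <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stopf("non-numeric detection cells in %s", path)
  rownames(m) <- sp
  if (!is.null(is_species_complex) && !is.null(names(is_species_complex)))
    is_species_complex <- unname(is_species_complex[sp])
  detection_matrix(m, is_species_complex = is_species_complex)
}

#' Write a detection table as TSV
#'
#' @param m a [detection_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_detection_table <- function(m, path) {
  df <- data.frame(species = rownames(m$mat), m$mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy read counts to a common depth
#'
#' Per site, subsamples reads without replacement down to exactly `depth`
#' (a multivariate hypergeometric draw across species). Sites whose total
#' read count is below `depth` are left unchanged and reported.
#'
#' @param m a count-mode [detection_matrix()].
#' @param depth target reads per site (>= 1).
#' @param seed integer seed.
#' @return a count-mode detection matrix; the ids of sites left unrarefied
#'   are in attribute `unrarefied_sites` and are also raised as a warning.
#' @export
rarefy_counts <- function(m, depth, seed = 1) {
  if (!inherits(m, "detection_matrix")) stopf("`m` must be a detection_matrix")
  if (m$mode != "counts") stopf("rarefaction needs a count-mode matrix")
  if (depth < 1) stopf("`depth` must be >= 1")
  depth <- as.integer(depth)
  set.seed(seed)
  mat <- m$mat
  totals <- colSums(mat)
  skipped <- character(0)
  for (k in seq_len(ncol(mat))) {
    if (totals[k] < depth) {
      skipped <- c(skipped, colnames(mat)[k])
    } else if (totals[k] > depth) {
      pool <- rep.int(seq_len(nrow(mat)), mat[, k])
      keep <- sample(pool, depth)
      mat[, k] <- tabulate(keep, nbins = nrow(mat))
    }
  }
  if (length(skipped) > 0)
    warning(sprintf("%d site(s) with total reads below depth %d left unrarefied: %s",
                    length(skipped), depth,
                    paste(utils::head(skipped, 5L), collapse = ", ")),
            call. = FALSE)
  out <- detection_matrix(mat, mode = "counts",
                          is_species_complex = m$is_species_complex)
  attr(out, "unrarefied_sites") <- skipped
  out
}

#' Occupancy and species-complex filtering
#'
#' Removes (1) species flagged as unresolved species complexes and
#' (2) species occurring at fewer than `min_sites` sites. Occupancy is
#' computed once on the input; the filter is a single pass, not iterated.
#'
#' @param m a [detection_matrix()].
#' @param min_sites minimum occupancy to retain a species (default 6, i.e.
#'   species at fewer than six sites are dropped).
#' @param drop_complexes drop species-complex rows?
#' @return list with `detections` (filtered matrix) and `report`
#'   (data frame of removed species ids with reasons).
#' @export
filter_species <- function(m, min_sites = 6, drop_complexes = TRUE) {
  if (!inherits(m, "detection_matrix")) stopf("`m` must be a detection_matrix")
  if (min_sites < 1) stopf("`min_sites` must be >= 1")
  occupancy <- rowSums(m$mat > 0)
  reason <- rep(NA_character_, nrow(m$mat))
  if (drop_complexes) reason[m$is_species_complex] <- "species_complex"
  rare <- is.na(reason) & occupancy < min_sites
  reason[rare] <- "below_min_sites"
  drop <- !is.na(reason)
  report <- data.frame(species = rownames(m$mat)[drop],
                       reason = reason[drop],
                       occupancy = unname(occupancy[drop]),
                       stringsAsFactors = FALSE)
  kept <- detection_matrix(m$mat[!drop, , drop = FALSE], mode = m$mode,
                           is_species_complex = m$is_species_complex[!drop])
  list(detections = kept, report = report)
}

#' Drop sites with missing required covariates
#'
#' Removes from both the detection matrix and the site table every site with
#' a missing value in any required covariate (e.g. instrument failure in the
#' field).
#'
#' @param m a [detection_matrix()].
#' @param sites a [site_table()] whose `site` ids match `colnames(m$mat)`.
#' @param required_covariates covariate column names that must be non-missing.
#' @return list with `detections`, `sites` and `report` (removed site ids
#'   with the offending covariates).
#' @export
filter_sites <- function(m, sites,
                         required_covariates = covariate_names(sites)) {
  if (!inherits(m, "detection_matrix")) stopf("`m` must be a detection_matrix")
  if (!setequal(colnames(m$mat), sites$site))
    stopf("site ids of the detection matrix and site table do not match")
  miss <- setdiff(required_covariates, names(sites))
  if (length(miss) > 0)
    stopf("required covariates absent from site table: %s",
          paste(miss, collapse = ", "))
  sites <- sites[match(colnames(m$mat), sites$site), , drop = FALSE]
  bad <- rep(FALSE, nrow(sites))
  why <- character(nrow(sites))
  for (cv in required_covariates) {
    na <- is.na(sites[[cv]])
    why[na & !bad] <- cv
    bad <- bad | na
  }
  report <- data.frame(site = sites$site[bad], missing = why[bad],
                       stringsAsFactors = FALSE)
  keep_sites <- sites[!bad, , drop = FALSE]
  out_sites <- site_table(keep_sites, distance = attr(sites, "distance"),
                          districts = attr(sites, "districts"))
  kept <- detection_matrix(m$mat[, !bad, drop = FALSE], mode = m$mode,
                           is_species_complex = m$is_species_complex)
  list(detections = kept, sites = out_sites, report = report)
}

#' Per-site species richness
#'
#' @param m a [detection_matrix()].
#' @return named integer vector: number of species detected at each site.
#' @export
site_richness <- function(m) {
  if (!inherits(m, "detection_matrix")) stopf("`m` must be a detection_matrix")
  colSums(m$mat > 0)
}

#' Jaccard distances between sites
#'
#' \eqn{d(a,b) = 1 - |A \cap B| / |A \cup B|} on the presence sets of each
#' site pair (counts are binarized first). A pair of sites with no species
#' at all is assigned distance 0 by convention.
#'
#' @param m a [detection_matrix()].
#' @return symmetric n_sites x n_sites distance matrix with zero diagonal.
#' @export
jaccard_distances <- function(m) {
  if (!inherits(m, "detection_matrix")) stopf("`m` must be a detection_matrix")
  b <- (m$mat > 0) * 1
  inter <- crossprod(b)                  # shared species per site pair
  n_sp <- colSums(b)
  uni <- outer(n_sp, n_sp, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  diag(d) <- 0
  d
}
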