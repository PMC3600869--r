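# Domain types shared by all stages: monitoring networks, observation sets,
# variable transforms, grids/population rasters and regulatory thresholds.

#' Monitoring station network
#'
#' Describes an (possibly unbalanced, heterotopic) monitoring network: each
#' pollutant has its own set of stations, and the site sets may differ or even
#' be disjoint. Internally the network is flattened into `N = sum(n_i)`
#' *entries*, one per (pollutant, station) pair, ordered by pollutant block.
#'
#' @param sites data.frame with columns `pollutant`, `station`, `lon`, `lat`.
#'   For planar networks `lon`/`lat` are easting/northing in km.
#' @param pollutants character vector fixing the pollutant order; defaults to
#'   order of first appearance.
#' @param dist_method `"haversine"` (lon/lat degrees, great-circle km) or
#'   `"planar"` (coordinates already in km).
#' @return An object of class `dcm_network`.
#' @export
dcm_network <- function(sites, pollutants = NULL, dist_method = c("haversine", "planar")) {
  dist_method <- match.arg(dist_method)
  stopifnot(is.data.frame(sites), all(c("pollutant", "station", "lon", "lat") %in% names(sites)))
  if (!all(is.finite(sites$lon)) || !all(is.finite(sites$lat)))
    stop("all station coordinates must be finite")
  if (is.null(pollutants)) pollutants <- unique(as.character(sites$pollutant))
  sites$pollutant <- as.character(sites$pollutant)
  if (!all(sites$pollutant %in% pollutants))
    stop("sites contain pollutants not listed in `pollutants`")
  for (p in pollutants) {
    ids <- sites$station[sites$pollutant == p]
    if (length(ids) < 1L) stop("pollutant ", p, " has no stations")
    if (anyDuplicated(ids)) stop("duplicated station ids within pollutant ", p)
  }
  # canonical entry order: pollutant block, then input order of stations
  ord <- order(match(sites$pollutant, pollutants))
  sites <- sites[ord, , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(
    sites = sites,
    pollutants = pollutants,
    dist_method = dist_method
  ), class = "dcm_network")
}

#' @export
print.dcm_network <- function(x, ...) {
  n <- table(factor(x$sites$pollutant, levels = x$pollutants))
  cat("dcm_network:", length(x$pollutants), "pollutants,",
      nrow(x$sites), "entries (", paste(n, collapse = "/"), "),",
      x$dist_method, "distances\n")
  invisible(x)
}

n_entries <- function(network) nrow(network$sites)

#' Per-entry pollutant index (1..q) in canonical entry order
#' @param network a `dcm_network`
#' @return integer vector of length N
#' @export
entry_pollutant <- function(network) {
  match(network$sites$pollutant, network$pollutants)
}

#' Station counts per pollutant
#' @param network a `dcm_network`
#' @return named integer vector
#' @export
station_counts <- function(network) {
  tab <- table(factor(network$sites$pollutant, levels = network$pollutants))
  setNames(as.integer(tab), network$pollutants)
}

#' Great-circle (haversine) distance matrix in km
#' @param lon,lat coordinate vectors in degrees
#' @return symmetric distance matrix (km)
#' @export
haversine_distance <- function(lon, lat) {
  rad <- pi / 180
  phi <- lat * rad; lam <- lon * rad
  dphi <- outer(phi, phi, "-") / 2
  dlam <- outer(lam, lam, "-") / 2
  a <- sin(dphi)^2 + outer(cos(phi), cos(phi)) * sin(dlam)^2
  a[a > 1] <- 1
  6371.0088 * 2 * asin(sqrt(a))
}

#' Inter-entry distance matrix for a network (km)
#' @param network a `dcm_network`
#' @return N x N matrix
#' @export
network_distances <- function(network) {
  s <- network$sites
  if (network$dist_method == "haversine") {
    haversine_distance(s$lon, s$lat)
  } else {
    dx <- outer(s$lon, s$lon, "-"); dy <- outer(s$lat, s$lat, "-")
    sqrt(dx^2 + dy^2)
  }
}

# distances (km) from arbitrary target coordinates to network entries
cross_distances <- function(network, lon, lat) {
  s <- network$sites
  if (network$dist_method == "haversine") {
    rad <- pi / 180
    phi1 <- lat * rad; phi2 <- s$lat * rad
    dphi <- outer(phi1, phi2, "-") / 2
    dlam <- outer(lon * rad, s$lon * rad, "-") / 2
    a <- sin(dphi)^2 + outer(cos(phi1), cos(phi2)) * sin(dlam)^2
    a[a > 1] <- 1
    6371.0088 * 2 * asin(sqrt(a))
  } else {
    dx <- outer(lon, s$lon, "-"); dy <- outer(lat, s$lat, "-")
    sqrt(dx^2 + dy^2)
  }
}

#' Multivariate station observation set
#'
#' Holds the N x T matrix `Y` of daily values over the network entries
#' (canonical pollutant-block order), with `NA` marking missing data. Time is
#' a strictly increasing daily index.
#'
#' @param network a [dcm_network()]
#' @param dates `Date` vector of length T (consecutive days) or integer index
#' @param values N x T numeric matrix, `NA` = missing
#' @param transform optional `dcm_transform` record attached to the values
#' @return An object of class `dcm_observations`.
#' @export
dcm_observations <- function(network, dates, values, transform = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != n_entries(network))
    stop("values must have one row per network entry (", n_entries(network), ")")
  if (ncol(values) != length(dates))
    stop("values must have one column per date")
  if (inherits(dates, "Date")) {
    if (length(dates) > 1 && any(diff(as.integer(dates)) != 1L))
      stop("dates must be consecutive days")
  } else {
    dates <- as.integer(dates)
    if (length(dates) > 1 && any(diff(dates) != 1L))
      stop("time index must be strictly increasing with unit step")
  }
  structure(list(network = network, dates = dates, values = values,
                 transform = transform),
            class = "dcm_observations")
}

#' @export
print.dcm_observations <- function(x, ...) {
  cat("dcm_observations:", nrow(x$values), "entries x", ncol(x$values), "days; ",
      sprintf("%.1f%% missing", 100 * mean(is.na(x$values))),
      if (!is.null(x$transform)) "(transformed)" else "", "\n")
  invisible(x)
}

#' Aggregate hourly values to a daily value under the 75% completeness rule
#'
#' A day is valid only if at least 18 of its (up to) 24 hourly values are
#' non-missing; valid days get the arithmetic mean of the available hours,
#' invalid days are missing.
#'
#' @param hourly numeric vector of at most 24 hourly values (`NA` = missing)
#' @param min_hours minimum number of valid hours (default 18, i.e. 75%)
#' @return daily mean, or `NA_real_` when below the completeness rule
#' @export
aggregate_hourly_to_daily <- function(hourly, min_hours = 18L) {
  if (length(hourly) > 24L)
    stop("malformed input: more than 24 hourly values in one day")
  ok <- !is.na(hourly)
  if (sum(ok) >= min_hours) mean(hourly[ok]) else NA_real_
}

#' Log-transform and standardize observations per variable
#'
#' Applies, per pollutant across its whole sub-network (network-wide, not
#' per-station), an optional natural-log transform followed by
#' standardization to sample mean 0 and sample standard deviation 1 over the
#' non-missing entries. The divisor convention is n-1 (the [stats::sd()]
#' convention) and is recorded in the returned transform record together with
#' the centering/scale constants, so the transform is exactly invertible.
#'
#' @param obs a [dcm_observations()] on the original concentration scale
#' @param log which variables get the log transform: logical scalar or vector
#'   per pollutant
#' @return a `dcm_observations` with transformed values and a `dcm_transform`
#'   record in `$transform`
#' @export
log_standardize <- function(obs, log = TRUE) {
  stopifnot(inherits(obs, "dcm_observations"))
  if (!is.null(obs$transform)) stop("observations are already transformed")
  q <- length(obs$network$pollutants)
  log <- rep_len(log, q)
  pol <- entry_pollutant(obs$network)
  vals <- obs$values
  center <- numeric(q); scale <- numeric(q)
  for (i in seq_len(q)) {
    rows <- which(pol == i)
    x <- vals[rows, , drop = FALSE]
    if (log[i]) {
      bad <- which(!is.na(x) & x <= 0, arr.ind = TRUE)
      if (nrow(bad) > 0) {
        stop(sprintf(
          "non-positive value under log transform: pollutant %s, station %s, day %d",
          obs$network$pollutants[i],
          obs$network$sites$station[rows[bad[1, 1]]], bad[1, 2]))
      }
      x <- base::log(x)
    }
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(as.vector(x), na.rm = TRUE)
    if (!is.finite(s) || s < 1e-12)
      stop("zero variance series for pollutant ", obs$network$pollutants[i])
    center[i] <- m; scale[i] <- s
    vals[rows, ] <- (x - m) / s
  }
  rec <- structure(list(log = log, center = center, scale = scale,
                        divisor = "n-1",
                        pollutants = obs$network$pollutants),
                   class = "dcm_transform")
  dcm_observations(obs$network, obs$dates, vals, transform = rec)
}

#' Invert a log-standardize transform
#'
#' @param x numeric values on the transformed scale
#' @param record a `dcm_transform` record
#' @param pollutant pollutant name or index the values belong to
#' @return values on the original concentration scale
#' @export
invert_transform <- function(x, record, pollutant) {
  i <- if (is.character(pollutant)) match(pollutant, record$pollutants) else pollutant
  if (is.na(i)) stop("unknown pollutant in transform record")
  y <- x * record$scale[i] + record$center[i]
  if (record$log[i]) exp(y) else y
}

#' Map an original-scale value onto the transformed (model) scale
#' @inheritParams invert_transform
#' @export
apply_transform <- function(x, record, pollutant) {
  i <- if (is.character(pollutant)) match(pollutant, record$pollutants) else pollutant
  if (is.na(i)) stop("unknown pollutant in transform record")
  if (record$log[i]) {
    if (any(x <= 0, na.rm = TRUE)) stop("non-positive value under log transform")
    x <- base::log(x)
  }
  (x - record$center[i]) / record$scale[i]
}

#' Back-transform observations to the original scale
#' @param obs a transformed `dcm_observations`
#' @return a `dcm_observations` on the original scale (no transform record)
#' @export
invert_observations <- function(obs) {
  stopifnot(inherits(obs, "dcm_observations"))
  if (is.null(obs$transform)) return(obs)
  pol <- entry_pollutant(obs$network)
  vals <- obs$values
  for (i in seq_along(obs$network$pollutants)) {
    rows <- pol == i
    vals[rows, ] <- invert_transform(vals[rows, , drop = FALSE], obs$transform, i)
  }
  dcm_observations(obs$network, obs$dates, vals)
}

#' Validate an observation set (report only, never mutates)
#'
#' @param obs a [dcm_observations()]
#' @return list with per-pollutant station counts, missing fractions,
#'   duplicated coordinates, fully-missing stations and days with no
#'   observation on any variable
#' @export
validate_observations <- function(obs) {
  stopifnot(inherits(obs, "dcm_observations"))
  net <- obs$network
  pol <- entry_pollutant(net)
  q <- length(net$pollutants)
  counts <- station_counts(net)
  missfrac <- vapply(seq_len(q), function(i)
    mean(is.na(obs$values[pol == i, , drop = FALSE])), numeric(1))
  names(missfrac) <- net$pollutants
  coords <- paste(net$sites$pollutant, net$sites$lon, net$sites$lat)
  dup <- net$sites[duplicated(coords) | duplicated(coords, fromLast = TRUE), , drop = FALSE]
  all_missing <- net$sites$station[rowSums(!is.na(obs$values)) == 0L]
  empty_days <- which(colSums(!is.na(obs$values)) == 0L)
  list(station_counts = counts,
       missing_fraction = missfrac,
       duplicated_coordinates = dup,
       fully_missing_stations = all_missing,
       empty_days = empty_days,
       n_days = ncol(obs$values))
}

#' Prediction grid with population counts
#'
#' A rectangular cell-centre grid with an optional region mask and a
#' time-invariant population count per cell. Serves as both the prediction
#' grid specification and the population raster.
#'
#' @param lon,lat cell-centre coordinates (degrees, or km when planar)
#' @param population non-negative population count per cell (persons)
#' @param mask logical region-mask per cell (default all `TRUE`)
#' @param dist_method coordinate convention, as in [dcm_network()]
#' @return An object of class `dcm_grid`.
#' @export
dcm_grid <- function(lon, lat, population = NULL, mask = NULL,
                     dist_method = c("haversine", "planar")) {
  dist_method <- match.arg(dist_method)
  n <- length(lon)
  stopifnot(length(lat) == n)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (is.null(population)) population <- rep(0, n)
  if (any(population < 0, na.rm = TRUE)) stop("population must be >= 0 everywhere")
  structure(list(lon = lon, lat = lat, population = population,
                 mask = mask, dist_method = dist_method),
            class = "dcm_grid")
}

#' Total population of the masked region
#' @param grid a `dcm_grid`
#' @export
total_population <- function(grid) sum(grid$population[grid$mask])

#' @export
print.dcm_grid <- function(x, ...) {
  cat("dcm_grid:", length(x$lon), "cells (", sum(x$mask), "in mask ), population",
      format(total_population(x), big.mark = ","), "\n")
  invisible(x)
}

#' Regulatory thresholds and index scaling factors
#'
#' @param L named per-pollutant exceedance threshold, original scale (ug/m3)
#' @param M day-count limit (days, non-negative integer); default 7
#' @param F named per-pollutant scaling factor (ug/m3 per index unit)
#' @return An object of class `dcm_thresholds`.
#' @export
dcm_thresholds <- function(L, M = 7L, F = NULL) {
  stopifnot(all(L > 0), M >= 0, M == round(M))
  if (!is.null(F)) stopifnot(all(F > 0))
  structure(list(L = L, M = as.integer(M), F = F), class = "dcm_thresholds")
}

#' Covariate field at stations and (optionally) on the prediction grid
#'
#' @param names covariate names
#' @param station array N x k x T of covariate values at the network entries
#' @param grid optional array ncell x k x T on the prediction grid
#' @return An object of class `dcm_covariates`.
#' @export
dcm_covariates <- function(names, station, grid = NULL) {
  station <- as_cov_array(station, length(names))
  if (anyNA(station)) stop("missing covariate values at stations are not allowed")
  if (!is.null(grid)) {
    grid <- as_cov_array(grid, length(names))
    if (dim(grid)[2] != dim(station)[2])
      stop("covariate count differs between station and grid views")
  }
  structure(list(names = names, station = station, grid = grid),
            class = "dcm_covariates")
}

as_cov_array <- function(x, k) {
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L || dim(x)[2] != k)
    stop("covariate array must be (units) x (covariates) x (days)")
  x
}
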