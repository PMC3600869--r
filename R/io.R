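# Delimited-text interfaces: long-format observation tables (with an hourly
# variant aggregated under the 75% completeness rule), grid/population
# rasters as cell-centre tables, and JSON round-tripping of parameter sets
# and run configurations.

#' Read a long-format observation table
#'
#' Expected columns: `station_id`, `lon`, `lat`, `date` (ISO-8601 or
#' integer), `pollutant`, `value`; the hourly variant adds `hour` and is
#' aggregated to daily means under the 18-hour completeness rule. Missing
#' days are implied by absent rows (or an empty `value`).
#'
#' @param path CSV file path
#' @param pollutants optional pollutant ordering
#' @param dist_method distance convention for the resulting network
#' @param hourly aggregate an hourly table to daily values
#' @return a [dcm_observations()]
#' @export
read_observations_csv <- function(path, pollutants = NULL,
                                  dist_method = c("haversine", "planar"),
                                  hourly = FALSE) {
  dist_method <- match.arg(dist_method)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "lon", "lat", "date", "pollutant", "value")
  if (hourly) need <- c(need, "hour")
  if (!all(need %in% names(df)))
    stop("missing columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  if (hourly) {
    key <- interaction(df$pollutant, df$station_id, df$date, drop = TRUE)
    agg <- tapply(df$value, key, aggregate_hourly_to_daily)
    first <- !duplicated(key)
    df <- df[first, c("station_id", "lon", "lat", "date", "pollutant")]
    df$value <- as.numeric(agg[as.character(key[first])])
  }
  skey <- paste(df$pollutant, df$station_id)
  first <- !duplicated(skey)
  sites <- data.frame(pollutant = df$pollutant[first],
                      station = df$station_id[first],
                      lon = df$lon[first], lat = df$lat[first])
  net <- dcm_network(sites, pollutants, dist_method)
  is_date <- any(grepl("-", df$date))
  dt <- if (is_date) as.Date(df$date) else as.integer(df$date)
  dates <- seq(min(dt), max(dt), by = 1)
  Y <- matrix(NA_real_, n_entries(net), length(dates))
  ekey <- paste(net$sites$pollutant, net$sites$station)
  r <- match(skey, ekey)
  cc <- match(as.integer(dt), as.integer(dates))
  keep <- !is.na(df$value)
  Y[cbind(r[keep], cc[keep])] <- df$value[keep]
  dcm_observations(net, dates, Y)
}

#' Write observations to a long-format CSV
#' @param obs a [dcm_observations()]
#' @param path output path
#' @export
write_observations_csv <- function(obs, path) {
  s <- obs$network$sites
  Tn <- ncol(obs$values)
  df <- data.frame(
    station_id = rep(s$station, Tn),
    lon = rep(s$lon, Tn), lat = rep(s$lat, Tn),
    date = rep(obs$dates, each = nrow(s)),
    pollutant = rep(s$pollutant, Tn),
    value = as.vector(obs$values))
  df <- df[!is.na(df$value), , drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a grid/population raster from its cell-centre text fallback
#'
#' Columns: `cell_lon`, `cell_lat`, `value` (population count), optional
#' logical `mask`.
#'
#' @param path CSV path
#' @param dist_method coordinate convention
#' @return a [dcm_grid()]
#' @export
read_grid_csv <- function(path, dist_method = c("haversine", "planar")) {
  dist_method <- match.arg(dist_method)
  df <- read.csv(path)
  stopifnot(all(c("cell_lon", "cell_lat", "value") %in% names(df)))
  dcm_grid(df$cell_lon, df$cell_lat, population = df$value,
           mask = if ("mask" %in% names(df)) as.logical(df$mask),
           dist_method = dist_method)
}

#' Write a grid/population raster to the cell-centre text fallback
#' @param grid a [dcm_grid()]
#' @param path output path
#' @export
write_grid_csv <- function(grid, path) {
  write.csv(data.frame(cell_lon = grid$lon, cell_lat = grid$lat,
                       value = grid$population, mask = grid$mask),
            path, row.names = FALSE)
  invisible(path)
}

# parameter sets as plain JSON-able lists
psi_to_list <- function(psi) {
  cfg <- psi$config
  list(config = list(q = cfg$q, p = cfg$p, pollutants = cfg$pollutants,
                     K = cfg$K, include_u = cfg$include_u,
                     include_w = cfg$include_w, n_lcm = cfg$n_lcm),
       beta = psi$beta, G = psi$G, Sigma_eta = psi$Sigma_eta,
       alpha = psi$alpha, theta = psi$theta, lambda = psi$lambda,
       V = psi$V, theta_tilde = psi$theta_tilde, sigma2 = psi$sigma2)
}

psi_from_list <- function(x) {
  cf <- x$config
  cfg <- dcm_config(q = cf$q, p = cf$p, pollutants = unlist(cf$pollutants),
                    K = matrix(unlist(cf$K), cf$q, cf$p),
                    include_u = isTRUE(cf$include_u),
                    include_w = isTRUE(cf$include_w),
                    n_lcm = max(1L, cf$n_lcm))
  m <- function(a, nr) if (is.null(a)) NULL else matrix(unlist(a), nrow = nr)
  dcm_parameters(cfg,
                 beta = if (!is.null(x$beta)) m(x$beta, length(unlist(x$beta)) / cf$q),
                 G = m(x$G, cf$p), Sigma_eta = m(x$Sigma_eta, cf$p),
                 alpha = if (!is.null(x$alpha)) unlist(x$alpha),
                 theta = if (!is.null(x$theta)) unlist(x$theta),
                 lambda = if (!is.null(x$lambda)) unlist(x$lambda),
                 V = if (!is.null(x$V)) lapply(x$V, function(v) m(v, cf$q)),
                 theta_tilde = if (!is.null(x$theta_tilde)) unlist(x$theta_tilde),
                 sigma2 = unlist(x$sigma2))
}

#' Save / load a parameter set as JSON
#' @param psi a [dcm_parameters()]
#' @param path JSON path
#' @export
write_parameters_json <- function(psi, path) {
  jsonlite::write_json(psi_to_list(psi), path, digits = NA, auto_unbox = TRUE,
                       matrix = "columnmajor")
  invisible(path)
}

#' @rdname write_parameters_json
#' @export
read_parameters_json <- function(path) {
  psi_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}
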