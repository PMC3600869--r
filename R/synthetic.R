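# Synthetic scenarios: planar country-scale networks with clustered
# population, smooth space-time covariate fields and observations simulated
# from a known parameter set, emulating the statistical structure of a
# three-pollutant national monitoring campaign (unbalanced network, stations
# preferentially in populated areas, 12-16% missing daily data, six
# covariates including population).

# Gaussian random field with exponential correlation, simulated on a coarse
# node grid and interpolated bilinearly to arbitrary points
grf_sampler <- function(xmax, ymax, range_km, nodes = 12L) {
  nx <- seq(0, xmax, length.out = nodes)
  ny <- seq(0, ymax, length.out = nodes)
  gr <- expand.grid(x = nx, y = ny)
  D <- as.matrix(dist(gr))
  L <- chol_psd(exp(-D / range_km))
  Z <- matrix(L %*% rnorm(nrow(gr)), nodes, nodes)
  function(x, y) {
    ix <- pmin(pmax(findInterval(x, nx), 1L), nodes - 1L)
    iy <- pmin(pmax(findInterval(y, ny), 1L), nodes - 1L)
    tx <- (x - nx[ix]) / (nx[ix + 1] - nx[ix])
    ty <- (y - ny[iy]) / (ny[iy + 1] - ny[iy])
    Z[cbind(ix, iy)] * (1 - tx) * (1 - ty) +
      Z[cbind(ix + 1, iy)] * tx * (1 - ty) +
      Z[cbind(ix, iy + 1)] * (1 - tx) * ty +
      Z[cbind(ix + 1, iy + 1)] * tx * ty
  }
}

#' Default true parameters for synthetic scenarios
#'
#' Fixture constants with the magnitudes a national multi-pollutant fit on
#' standardized log concentrations tends to produce: regression coefficients
#' of a few tenths, a moderately persistent diagonal transition (0.35-0.6),
#' a single shared coregionalization component with a range of 50 km whose
#' scale gives the spatial field about half of the residual variability,
#' negative cross-correlation between the ozone-like component and the
#' others, and a measurement-noise share of about 25%.
#'
#' @param q number of pollutants
#' @param k number of covariates
#' @param pollutants pollutant names
#' @return a [dcm_parameters()] with its [dcm_config()] (w included, u not)
#' @export
default_scenario_parameters <- function(q = 3L, k = 6L,
                                        pollutants = c("NO2", "O3", "PM10")[seq_len(q)]) {
  cfg <- dcm_config(q = q, p = q, pollutants = pollutants,
                    include_u = FALSE, include_w = TRUE, n_lcm = 1L)
  beta_bank <- cbind(c(0.45, 0.31, -0.42, -0.19, -0.21, 0.32),
                     c(-0.17, 0.37, -0.25, 0.21, 0.19, -0.20),
                     c(0.09, 0.27, 0.38, -0.29, -0.06, -0.23))
  beta <- matrix(rep(beta_bank, length.out = k * q), k, q)
  g_bank <- c(0.5, 0.6, 0.35)
  G <- diag(rep(g_bank, length.out = q), q)
  Se <- diag(rep(c(0.02, 0.02, 0.06), length.out = q), q)
  V <- diag(q)
  if (q >= 2) V[1, 2] <- V[2, 1] <- 0.5
  if (q >= 3) {
    V[1, 3] <- V[3, 1] <- -0.40
    V[2, 3] <- V[3, 2] <- -0.35
    # row/col 2 is the ozone-like component; make it the negative one
    V[1, 2] <- V[2, 1] <- -0.35; V[1, 3] <- V[3, 1] <- 0.5
    V[2, 3] <- V[3, 2] <- -0.40
  }
  dcm_parameters(cfg, beta = beta, G = G, Sigma_eta = Se,
                 lambda = rep(0.7, q), V = list(V), theta_tilde = 50,
                 sigma2 = rep(0.25, q))
}

#' Generate a synthetic monitoring scenario
#'
#' Builds, reproducibly from a seed: a clustered population raster on a
#' planar km grid; an unbalanced station network placed with probability
#' proportional to population^gamma (preferential urban placement); smooth
#' space-time covariate fields (Gaussian random fields plus an AR(1) temporal
#' signal) with log-population as the last covariate; and observations
#' simulated from the true parameter set with independent per-pollutant
#' missingness. Defaults follow a scaled three-pollutant national campaign:
#' 12/4/10 stations, 120 days, missing rates 12.7/12.1/16.1%, six
#' covariates.
#'
#' @param q number of pollutants
#' @param stations station count per pollutant
#' @param T number of days
#' @param missing per-pollutant missingness probability
#' @param grid_dim grid dimensions (cells in x and y)
#' @param cell_km cell size (km)
#' @param n_clusters population clusters
#' @param n_covariates covariate count (the last is log-population)
#' @param total_pop total population of the region
#' @param gamma station-placement preferential exponent
#' @param psi `"default"` ([default_scenario_parameters()]) or a
#'   [dcm_parameters()]
#' @param seed RNG seed (same seed + config: identical scenario)
#' @param grid_truth also simulate the noise-free true concentration field
#'   at every masked grid cell (costly; used by calibration checks)
#' @return `dcm_scenario` list: `network`, `grid`, `covariates`, `psi`,
#'   `config`, `obs` (transformed scale, with a synthetic log-standardize
#'   record attached), `latent`, and `truth_grid` (per-pollutant cells x T
#'   noise-free field, when requested)
#' @export
make_scenario <- function(q = 3L, stations = c(12L, 4L, 10L), T = 120L,
                          missing = c(0.127, 0.121, 0.161),
                          grid_dim = c(40L, 40L), cell_km = 5,
                          n_clusters = 5L, n_covariates = 6L,
                          total_pop = 5e6, gamma = 1,
                          psi = "default", seed = 1L, grid_truth = FALSE) {
  stopifnot(length(stations) == q)
  set.seed(seed)
  if (identical(psi, "default"))
    psi <- default_scenario_parameters(q, n_covariates)
  cfg <- psi$config
  pollutants <- cfg$pollutants
  missing <- rep_len(missing, q)

  nx <- grid_dim[1]; ny <- grid_dim[2]
  gx <- ((seq_len(nx)) - 0.5) * cell_km
  gy <- ((seq_len(ny)) - 0.5) * cell_km
  cells <- expand.grid(lon = gx, lat = gy)
  ncell <- nrow(cells)
  if (any(stations > ncell)) stop("more stations than grid cells")

  # clustered population
  cx <- runif(n_clusters, 0.1, 0.9) * max(gx)
  cy <- runif(n_clusters, 0.1, 0.9) * max(gy)
  cs <- runif(n_clusters, 8, 25)
  cwt <- rgamma(n_clusters, shape = 2)
  pop_raw <- rep(0.02 / ncell, ncell)
  for (j in seq_len(n_clusters))
    pop_raw <- pop_raw + cwt[j] *
      exp(-((cells$lon - cx[j])^2 + (cells$lat - cy[j])^2) / (2 * cs[j]^2))
  pop <- round(total_pop * pop_raw / sum(pop_raw))
  grid <- dcm_grid(cells$lon, cells$lat, population = pop,
                   dist_method = "planar")

  # stations preferentially where people live
  sites <- NULL
  for (i in seq_len(q)) {
    pick <- sample.int(ncell, stations[i], prob = (pop + 1)^gamma)
    sites <- rbind(sites, data.frame(
      pollutant = pollutants[i],
      station = sprintf("%s_%02d", pollutants[i], seq_len(stations[i])),
      lon = cells$lon[pick] + runif(stations[i], -0.3, 0.3) * cell_km,
      lat = cells$lat[pick] + runif(stations[i], -0.3, 0.3) * cell_km))
  }
  network <- dcm_network(sites, pollutants, dist_method = "planar")
  N <- n_entries(network)

  # covariates: GRF + AR(1) temporal signal; last covariate = log population
  k <- n_covariates
  Xs <- array(0, dim = c(N, k, T))
  Xg <- array(0, dim = c(ncell, k, T))
  logpop <- log1p(pop)
  logpop <- (logpop - mean(logpop)) / sd(logpop)
  pop_at <- function(x, y) {
    ix <- pmin(pmax(round(x / cell_km + 0.5), 1L), nx)
    iy <- pmin(pmax(round(y / cell_km + 0.5), 1L), ny)
    logpop[(iy - 1L) * nx + ix]
  }
  for (kk in seq_len(k)) {
    if (kk == k) {
      Xs[, kk, ] <- pop_at(network$sites$lon, network$sites$lat)
      Xg[, kk, ] <- logpop
    } else {
      f <- grf_sampler(max(gx), max(gy), range_km = 30)
      b <- as.vector(stats::filter(rnorm(T, 0, 0.6 * sqrt(1 - 0.8^2)), 0.8,
                                   method = "recursive",
                                   init = rnorm(1, 0, 0.6)))
      fs <- 0.8 * f(network$sites$lon, network$sites$lat)
      fg <- 0.8 * f(cells$lon, cells$lat)
      Xs[, kk, ] <- outer(fs, rep(1, T)) + outer(rep(1, N), b)
      Xg[, kk, ] <- outer(fg, rep(1, T)) + outer(rep(1, ncell), b)
    }
  }
  covariates <- dcm_covariates(c(paste0("x", seq_len(k - 1)), "logpop"), Xs, Xg)

  sim_seed <- (seed * 1000L + 7L) %% .Machine$integer.max
  truth_grid <- NULL
  if (grid_truth) {
    mcells <- which(grid$mask)
    aug_sites <- sites
    for (i in seq_len(q)) {
      aug_sites <- rbind(aug_sites, data.frame(
        pollutant = pollutants[i],
        station = sprintf("%s_cell%05d", pollutants[i], mcells),
        lon = cells$lon[mcells], lat = cells$lat[mcells]))
    }
    aug_net <- dcm_network(aug_sites, pollutants, dist_method = "planar")
    # entry order within each pollutant block: real stations first, then
    # pseudo-stations in masked-cell order (dcm_network keeps input order)
    ord <- entry_pollutant(aug_net)
    is_cell <- grepl("_cell", aug_net$sites$station)
    Xa <- array(0, dim = c(n_entries(aug_net), k, T))
    Xa[!is_cell, , ] <- Xs
    cell_idx <- as.integer(sub(".*_cell", "", aug_net$sites$station[is_cell]))
    Xa[is_cell, , ] <- Xg[cell_idx, , ]
    aug_cov <- dcm_covariates(covariates$names, Xa)
    sim <- simulate_dcm(psi, aug_net, aug_cov, T = T,
                        missing = 0, seed = sim_seed)
    miss_draw <- matrix(runif(N * T), N, T) < missing[entry_pollutant(network)]
    Yst <- sim$obs$values[!is_cell, , drop = FALSE]
    Yst[miss_draw] <- NA_real_
    obs <- dcm_observations(network, seq_len(T), Yst)
    latent <- sim$latent
    truth_grid <- lapply(seq_len(q), function(i)
      sim$latent$signal[which(is_cell & ord == i), , drop = FALSE])
    names(truth_grid) <- pollutants
  } else {
    sim <- simulate_dcm(psi, network, covariates, T = T,
                        missing = missing, seed = sim_seed)
    obs <- sim$obs
    latent <- sim$latent
  }

  rec <- structure(list(log = rep(TRUE, q),
                        center = rep_len(c(3.2, 3.9, 2.7), q),
                        scale = rep_len(c(0.6, 0.35, 0.5), q),
                        divisor = "n-1", pollutants = pollutants),
                   class = "dcm_transform")
  obs$transform <- rec

  structure(list(network = network, grid = grid, covariates = covariates,
                 psi = psi, config = cfg, obs = obs, latent = latent,
                 truth_grid = truth_grid,
                 config_echo = list(q = q, stations = stations, T = T,
                                    missing = missing, grid_dim = grid_dim,
                                    cell_km = cell_km,
                                    n_clusters = n_clusters,
                                    n_covariates = n_covariates,
                                    total_pop = total_pop, gamma = gamma,
                                    seed = seed)),
            class = "dcm_scenario")
}

#' @export
print.dcm_scenario <- function(x, ...) {
  cat("dcm_scenario: seed", x$config_echo$seed, "-",
      paste(station_counts(x$network), collapse = "/"), "stations,",
      ncol(x$obs$values), "days,", length(x$grid$lon), "grid cells\n")
  invisible(x)
}

#' Fixed micro instance for brute-force oracles
#'
#' A deterministic tiny instance (2 pollutants at 3 shared stations, 4 days,
#' one missing value) small enough that every model quantity - likelihood,
#' smoothed states, kriging mean and variance - can be recomputed from the
#' dense joint Gaussian of all observations. Both spatial components and the
#' temporal state are active.
#'
#' @return list: `psi`, `config`, `network`, `covariates`, `obs`, `latent`
#' @export
make_micro_example <- function() {
  cfg <- dcm_config(q = 2L, p = 2L, pollutants = c("A", "B"),
                    include_u = TRUE, include_w = TRUE, n_lcm = 1L)
  psi <- dcm_parameters(cfg,
                        beta = matrix(c(0.5, -0.3), 1, 2),
                        G = matrix(c(0.6, 0, 0.1, 0.5), 2, 2),
                        Sigma_eta = matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2),
                        alpha = c(0.8, 0.6), theta = c(40, 60),
                        lambda = c(0.5, 0.7),
                        V = list(matrix(c(1, 0.4, 0.4, 1), 2, 2)),
                        theta_tilde = 35,
                        sigma2 = c(0.09, 0.16))
  coords <- data.frame(lon = c(0, 30, 10), lat = c(0, 5, 40))
  sites <- data.frame(pollutant = rep(c("A", "B"), each = 3),
                      station = rep(c("s1", "s2", "s3"), 2),
                      lon = rep(coords$lon, 2), lat = rep(coords$lat, 2))
  network <- dcm_network(sites, c("A", "B"), dist_method = "planar")
  T <- 4L
  # deterministic covariate: one smooth space-time surface
  xst <- outer(coords$lon + coords$lat, seq_len(T),
               function(s, t) sin(t / 2) + 0.02 * s)
  Xs <- array(rbind(xst, xst), dim = c(6, 1, T))
  covariates <- dcm_covariates("x1", Xs)
  sim <- simulate_dcm(psi, network, covariates, T = T, missing = 0, seed = 42)
  Y <- sim$obs$values
  Y[2, 3] <- NA_real_                     # exercise the missing-data path
  obs <- dcm_observations(network, seq_len(T), Y)
  list(psi = psi, config = cfg, network = network, covariates = covariates,
       obs = obs, latent = sim$latent)
}
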