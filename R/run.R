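# Reproducible pipeline stages tying the modules together. Each stage reads
# the artifacts of its upstream stage from a directory, writes delimited-text
# and JSON outputs, and echoes its configuration and seed next to them. The
# command-line entry point (inst/cli/dcmair.R) is a thin wrapper over these.

stage_echo <- function(dir, stage, config) {
  config$stage <- stage
  config$package_version <- as.character(utils::packageVersion("dcmair"))
  config$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(config, file.path(dir, paste0(stage, "_config.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

require_artifact <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact ", path,
         "; run the `", producer, "` command first", call. = FALSE)
  path
}

#' Pipeline stage: simulate a scenario to disk
#'
#' @param out output directory (created if needed)
#' @param seed scenario seed
#' @param ... passed to [make_scenario()]
#' @return the output directory, invisibly
#' @export
run_simulate <- function(out, seed = 1L, ...) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- make_scenario(seed = seed, ...)
  write_observations_csv(sc$obs, file.path(out, "observations.csv"))
  write_grid_csv(sc$grid, file.path(out, "population.csv"))
  write_parameters_json(sc$psi, file.path(out, "true_parameters.json"))
  saveRDS(sc, file.path(out, "scenario.rds"))   # full object for downstream stages
  stage_echo(out, "simulate", c(sc$config_echo, list(seed = seed)))
  invisible(out)
}

read_scenario <- function(dir) {
  readRDS(require_artifact(file.path(dir, "scenario.rds"), "simulate"))
}

#' Pipeline stage: fit the model to a simulated scenario
#'
#' @param scenario_dir directory written by [run_simulate()]
#' @param out output directory
#' @param maxit,tol EM control parameters
#' @param standard_errors also compute Fisher-information standard errors
#' @return the output directory, invisibly
#' @export
run_fit <- function(scenario_dir, out, maxit = 200L, tol = 1e-5,
                    standard_errors = FALSE) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- read_scenario(scenario_dir)
  fit <- em_fit(sc$obs, sc$covariates, sc$config,
                control = list(maxit = maxit, tol = tol))
  write_parameters_json(fit$psi, file.path(out, "parameters.json"))
  write.csv(data.frame(iteration = seq_along(fit$trace), loglik = fit$trace),
            file.path(out, "loglik_trace.csv"), row.names = FALSE)
  if (standard_errors) {
    fi <- fisher_information(fit)
    write.csv(data.frame(parameter = names(fi$sd), estimate = fi$par,
                         sd = fi$sd),
              file.path(out, "standard_errors.csv"), row.names = FALSE)
    fit$fisher <- fi
  }
  saveRDS(fit, file.path(out, "fit.rds"))
  stage_echo(out, "fit", list(scenario_dir = scenario_dir, maxit = maxit,
                              tol = tol, converged = fit$converged,
                              loglik = fit$loglik))
  invisible(out)
}

read_fit <- function(dir) readRDS(require_artifact(file.path(dir, "fit.rds"), "fit"))

#' Pipeline stage: dynamic kriging maps
#'
#' @param scenario_dir,fit_dir upstream artifact directories
#' @param out output directory
#' @return the output directory, invisibly
#' @export
run_krige <- function(scenario_dir, fit_dir, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- read_scenario(scenario_dir)
  fit <- read_fit(fit_dir)
  maps <- krige(fit, sc$grid)
  for (pn in names(maps)) {
    m <- maps[[pn]]
    df <- data.frame(
      cell = rep(m$cells, ncol(m$yhat)),
      cell_lon = rep(m$grid$lon[m$cells], ncol(m$yhat)),
      cell_lat = rep(m$grid$lat[m$cells], ncol(m$yhat)),
      date = rep(m$dates, each = length(m$cells)),
      yhat = as.vector(m$yhat), sd = as.vector(m$sd),
      yhat_orig = as.vector(m$yhat_orig))
    write.csv(df, file.path(out, paste0("map_", pn, ".csv")), row.names = FALSE)
  }
  saveRDS(maps, file.path(out, "maps.rds"))
  stage_echo(out, "krige", list(scenario_dir = scenario_dir, fit_dir = fit_dir))
  invisible(out)
}

read_maps <- function(dir) readRDS(require_artifact(file.path(dir, "maps.rds"), "krige"))

#' Pipeline stage: global air-quality indices
#'
#' @param scenario_dir upstream scenario directory
#' @param out output directory
#' @param seed Monte-Carlo seed for the I3 intervals
#' @return the output directory, invisibly
#' @export
run_indices <- function(scenario_dir, out, seed = 1L) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- read_scenario(scenario_dir)
  orig <- invert_observations(sc$obs)
  Fv <- default_scaling_factors(sc$network$pollutants)
  imod <- build_index_model(orig, F = Fv)
  i2 <- index_I2(imod)
  i3 <- index_I3(imod, seed = seed)
  out2 <- data.frame(date = i2$date, I2 = i2$value, I2_var = i2$var,
                     I2_lower = i2$lower, I2_upper = i2$upper,
                     I3 = i3$value, I3_pollutant = i3$argmax,
                     I3_lower = i3$lower, I3_upper = i3$upper)
  write.csv(out2, file.path(out, "indices.csv"), row.names = FALSE)
  stage_echo(out, "indices", list(scenario_dir = scenario_dir, seed = seed,
                                  scaling_factors = as.list(Fv)))
  invisible(out)
}

#' Pipeline stage: population exposure summaries
#'
#' @param scenario_dir,krige_dir upstream artifact directories
#' @param out output directory
#' @param thresholds a [dcm_thresholds()]; default 105/87/50 with M = 7
#' @return the output directory, invisibly
#' @export
run_exposure <- function(scenario_dir, krige_dir, out, thresholds = NULL) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- read_scenario(scenario_dir)
  maps <- read_maps(krige_dir)
  if (is.null(thresholds)) thresholds <- default_thresholds(sc$network$pollutants)
  rows <- lapply(names(maps), function(pn) {
    m <- maps[[pn]]
    avg <- temporal_average_map(m)
    ei <- exposure_index(avg, sc$grid, m$cells)
    ce <- cumulative_exposure(avg, sc$grid, m$cells)
    counts <- daily_exceedance_population(m$yhat_orig, sc$grid,
                                          thresholds$L[[pn]], m$cells)
    write.csv(data.frame(date = m$dates, exceeding_population = counts),
              file.path(out, paste0("daily_exceedance_", pn, ".csv")),
              row.names = FALSE)
    data.frame(pollutant = pn, region_average_exposure = ei$region,
               threshold = thresholds$L[[pn]],
               max_daily_exceeding_population = max(counts))
  })
  write.csv(do.call(rbind, rows), file.path(out, "exposure.csv"),
            row.names = FALSE)
  stage_echo(out, "exposure", list(scenario_dir = scenario_dir,
                                   krige_dir = krige_dir,
                                   L = as.list(thresholds$L), M = thresholds$M))
  invisible(out)
}

#' Default regulatory thresholds (daily scale)
#'
#' 105, 87 and 50 ug/m3 for NO2, O3 and PM10, with a 7-day count limit.
#' @param pollutants pollutant names (must be among NO2/O3/PM10 or supplied)
#' @param L optional named override
#' @export
default_thresholds <- function(pollutants, L = NULL) {
  base <- c(NO2 = 105, O3 = 87, PM10 = 50)
  if (is.null(L)) {
    if (!all(pollutants %in% names(base)))
      stop("no default threshold for ",
           paste(setdiff(pollutants, names(base)), collapse = ", "))
    L <- base[pollutants]
  }
  dcm_thresholds(L, M = 7L)
}

#' Pipeline stage: exceedance risk surfaces and aggregated series
#'
#' @param scenario_dir,fit_dir,krige_dir upstream artifact directories
#' @param out output directory
#' @param thresholds a [dcm_thresholds()]
#' @param R bootstrap replications for the aggregated-series bands (0 = none)
#' @param seed RNG seed
#' @return the output directory, invisibly
#' @export
run_risk <- function(scenario_dir, fit_dir, krige_dir, out,
                     thresholds = NULL, R = 0L, seed = 1L) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  sc <- read_scenario(scenario_dir)
  fit <- read_fit(fit_dir)
  maps <- read_maps(krige_dir)
  if (is.null(thresholds)) thresholds <- default_thresholds(sc$network$pollutants)
  cv <- loso_crossval(fit)
  rcdf <- fit_residual_cdf(cv)
  for (pn in names(maps)) {
    m <- maps[[pn]]
    pi <- exceedance_probability(m, thresholds$L[[pn]], rcdf)
    dc <- risk_day_counts(pi, M = thresholds$M, method = "montecarlo",
                          nsim = 500L, seed = seed)
    agg <- aggregated_risk_series(pi, sc$grid, m$cells)
    write.csv(cbind(data.frame(cell = m$cells,
                               cell_lon = m$grid$lon[m$cells],
                               cell_lat = m$grid$lat[m$cells]), dc),
              file.path(out, paste0("day_counts_", pn, ".csv")),
              row.names = FALSE)
    df <- data.frame(date = m$dates, risk = agg)
    if (R > 0) {
      fi <- fit$fisher
      if (is.null(fi)) fi <- fisher_information(fit, blocks = "beta")
      bb <- bootstrap_bands(fit, function(ps) {
        f2 <- fit; f2$psi <- ps
        mm <- krige(f2, sc$grid, pollutants = pn)[[pn]]
        aggregated_risk_series(
          exceedance_probability(mm, thresholds$L[[pn]], rcdf),
          sc$grid, mm$cells)
      }, R = R, seed = seed, fisher = fi)
      df$lower <- bb$lower; df$upper <- bb$upper
    }
    write.csv(df, file.path(out, paste0("aggregated_risk_", pn, ".csv")),
              row.names = FALSE)
  }
  write.csv(data.frame(pollutant = names(cv$cmse), cmse = cv$cmse,
                       insample_mse = cv$insample_mse),
            file.path(out, "crossval.csv"), row.names = FALSE)
  stage_echo(out, "risk", list(scenario_dir = scenario_dir, fit_dir = fit_dir,
                               krige_dir = krige_dir, R = R, seed = seed,
                               L = as.list(thresholds$L), M = thresholds$M))
  invisible(out)
}

#' Pipeline stage: one-page summary of all indices
#'
#' @param dirs named list/vector with the stage output directories
#'   (`indices`, `exposure`, `risk` entries used when present)
#' @param out output directory
#' @return path of the report, invisibly
#' @export
run_report <- function(dirs, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  rep <- list()
  if (!is.null(dirs$indices)) {
    ix <- read.csv(require_artifact(file.path(dirs$indices, "indices.csv"),
                                    "indices"))
    rep$air_quality_index <- list(
      mean_I3 = mean(ix$I3), max_I3 = max(ix$I3),
      worst_day = ix$date[which.max(ix$I3)],
      dominant_pollutant = names(which.max(table(ix$I3_pollutant))))
  }
  if (!is.null(dirs$exposure)) {
    ex <- read.csv(require_artifact(file.path(dirs$exposure, "exposure.csv"),
                                    "exposure"))
    rep$exposure <- ex
  }
  if (!is.null(dirs$risk)) {
    cvf <- require_artifact(file.path(dirs$risk, "crossval.csv"), "risk")
    rep$crossval <- read.csv(cvf)
  }
  path <- file.path(out, "report.json")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  stage_echo(out, "report", list(dirs = dirs))
  invisible(path)
}
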