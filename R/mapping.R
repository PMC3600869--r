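# Dynamic kriging over a prediction grid: plug-in conditional-normal
# prediction with prediction variances, block (change-of-support)
# aggregation by the pixel-centre rule, and temporal averaging.

#' Dynamic kriging maps
#'
#' Plug-in prediction of each pollutant at the masked grid cells for every
#' day: covariate mean + loading on the smoothed temporal state + conditional
#' expectation of the spatial components given all observed data. The
#' prediction variance combines the spatial conditional variance and the
#' smoothed-state uncertainty; no measurement-error term is included.
#'
#' @param fit a [em_fit()] result (its covariates must carry a grid view,
#'   unless the model has no covariates)
#' @param grid a [dcm_grid()]
#' @param pollutants which pollutants to map (names or indices; default all)
#' @param days integer subset of days (default all)
#' @param transform `dcm_transform` used to back-transform predictions;
#'   default the record attached to the fitted observations
#' @param backtransform `"lognormal"` (exp(m + s mu + s^2 var / 2), the
#'   lognormal mean, default), `"naive"` (plain inverse transform of the
#'   mean) or `"none"`
#' @param chunk number of cells per solve block (memory control)
#' @return named list of `dcm_map` objects, one per pollutant, each with
#'   `yhat`/`sd` on the model scale, `yhat_orig` on the original scale,
#'   the masked `cells` index and the grid reference
#' @export
krige <- function(fit, grid, pollutants = NULL, days = NULL,
                  transform = NULL, backtransform = c("lognormal", "naive", "none"),
                  chunk = 800L) {
  backtransform <- match.arg(backtransform)
  psi <- fit$psi; cfg <- fit$config
  obs <- fit$obs; net <- obs$network
  if (is.null(transform)) transform <- obs$transform
  pol <- entry_pollutant(net)
  Y <- obs$values; Tn <- ncol(Y)
  if (is.null(days)) days <- seq_len(Tn)
  if (is.null(pollutants)) pollutants <- cfg$pollutants
  if (is.numeric(pollutants)) pollutants <- cfg$pollutants[pollutants]
  H <- if (is.null(fit$H)) entry_loadings(cfg, pol) else fit$H
  mu <- if (is.null(psi$beta)) matrix(0, nrow(Y), Tn) else
    build_mean(psi, fit$covariates, pol)
  Sigma <- residual_covariance(psi, net)
  sm <- fit$smoother
  Z1 <- sm$z[, 2:(Tn + 1), drop = FALSE]
  E <- Y - mu - H %*% Z1

  cells <- which(grid$mask)
  if (!is.null(psi$beta)) {
    Xg <- fit$covariates$grid
    if (is.null(Xg)) stop("covariates have no grid view")
    bad <- cells[apply(is.na(Xg[cells, , , drop = FALSE]), 1, any)]
    if (length(bad)) {
      message(length(bad), " grid cells masked for missing covariates")
      cells <- setdiff(cells, bad)
    }
  }

  out <- list()
  for (pn in pollutants) {
    i <- match(pn, cfg$pollutants)
    pol0 <- rep(i, length(cells))
    mu0 <- if (is.null(psi$beta)) matrix(0, length(cells), Tn) else
      build_mean(psi, fit$covariates, pol0, view = "grid", rows = cells)
    H0 <- cfg$K[rep(i, length(cells)), , drop = FALSE]
    c0 <- prior_spatial_variance(psi, pol0)
    yhat <- sdv <- matrix(NA_real_, length(cells), Tn)
    for (start in seq(1, length(cells), by = chunk)) {
      ix <- start:min(start + chunk - 1L, length(cells))
      Dc <- cross_distances(net, grid$lon[cells[ix]], grid$lat[cells[ix]])
      C0 <- cross_spatial_covariance(psi, Dc, pol0[ix], pol)
      kr <- cpp_krige(E, H, Sigma, C0, c0[ix], H0[ix, , drop = FALSE], sm$P)
      yhat[ix, ] <- mu0[ix, , drop = FALSE] + H0[ix, , drop = FALSE] %*% Z1 + kr$adj
      sdv[ix, ] <- sqrt(kr$var)
    }
    yhat <- yhat[, days, drop = FALSE]; sdv <- sdv[, days, drop = FALSE]
    yorig <- NULL
    if (backtransform != "none" && !is.null(transform)) {
      m <- transform$center[i]; s <- transform$scale[i]
      yorig <- if (transform$log[i]) {
        if (backtransform == "lognormal")
          exp(m + s * yhat + s^2 * sdv^2 / 2)
        else exp(m + s * yhat)
      } else m + s * yhat
    }
    out[[pn]] <- structure(list(pollutant = pn, yhat = yhat, sd = sdv,
                                yhat_orig = yorig, cells = cells,
                                grid = grid, days = days,
                                dates = obs$dates[days],
                                transform = transform,
                                backtransform = backtransform),
                           class = "dcm_map")
  }
  out
}

#' @export
print.dcm_map <- function(x, ...) {
  cat("dcm_map:", x$pollutant, "-", length(x$cells), "cells x",
      ncol(x$yhat), "days\n")
  invisible(x)
}

#' Block aggregation (change of support)
#'
#' Aggregates cell-level values to blocks of a tessellation. The default
#' pixel-centre rule takes, per block, the value of the cell nearest the
#' block centroid; `mode = "mean"` averages the member cells (the k x k
#' sub-sampling approximation of the block integral). Empty blocks are `NA`.
#'
#' @param values vector (per cell) or cells x days matrix
#' @param lon,lat cell-centre coordinates aligned with `values` rows
#' @param blocks block membership (factor/integer per cell)
#' @param mode `"centre"` or `"mean"`
#' @return blocks x days matrix (row names = block levels)
#' @export
block_aggregate <- function(values, lon, lat, blocks, mode = c("centre", "mean")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  blocks <- as.factor(blocks)
  out <- matrix(NA_real_, nlevels(blocks), ncol(values),
                dimnames = list(levels(blocks), colnames(values)))
  for (b in levels(blocks)) {
    m <- which(blocks == b)
    if (!length(m)) next
    if (mode == "mean") {
      out[b, ] <- colMeans(values[m, , drop = FALSE])
    } else {
      cx <- mean(lon[m]); cy <- mean(lat[m])
      j <- m[which.min((lon[m] - cx)^2 + (lat[m] - cy)^2)]
      out[b, ] <- values[j, ]
    }
  }
  out
}

#' Temporal average of a dynamic map
#'
#' Per-cell arithmetic mean of the back-transformed daily predictions over a
#' set of days (a month, a season, a year).
#'
#' @param map a `dcm_map` from [krige()]
#' @param days subset of the map's day indices (default all)
#' @param scale `"original"` (back-transformed, default) or `"model"`
#' @return vector of per-cell averages aligned with `map$cells`
#' @export
temporal_average_map <- function(map, days = NULL, scale = c("original", "model")) {
  scale <- match.arg(scale)
  vals <- if (scale == "original") map$yhat_orig else map$yhat
  if (is.null(vals)) stop("map has no values on the requested scale")
  if (is.null(days)) days <- seq_len(ncol(vals))
  if (length(days) == 0) stop("empty day set")
  if (any(days < 1 | days > ncol(vals))) stop("day set outside the map's days")
  rowMeans(vals[, days, drop = FALSE])
}
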