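# Global air-quality indices: the reduced common-trend model with fixed
# station-average loadings, and the latent-state indices I1 (scalar state),
# I2 (mean of states) and I3 (max of states) with uncertainty.

#' Default index scaling factors
#'
#' Scaling factors F_i (ug/m3 per index unit) homogenize pollutants reported
#' with different statistics before the common-trend model is fitted. The
#' defaults anchor an index value of 10 at the banding-system concentrations:
#' 128 ug/m3 for PM10 (daily mean, F = 12.8), 764 ug/m3 for NO2 and 360
#' ug/m3 for O3, the latter two divided by a configurable conversion factor
#' between the banding statistic (hourly / running 8-h mean) and the daily
#' mean used here (default 1).
#'
#' @param pollutants pollutant names
#' @param conversion daily-to-statistic conversion factor for NO2 and O3
#' @param overrides named vector of user-supplied factors (respected verbatim)
#' @return named vector of scaling factors
#' @export
default_scaling_factors <- function(pollutants, conversion = 1, overrides = NULL) {
  base <- c(NO2 = 764 / 10, O3 = 360 / 10, PM10 = 128 / 10)
  out <- setNames(numeric(length(pollutants)), pollutants)
  for (pn in pollutants) {
    if (!is.null(overrides) && pn %in% names(overrides)) {
      out[pn] <- overrides[[pn]]
    } else if (pn %in% c("NO2", "O3")) {
      out[pn] <- base[[pn]] / conversion
    } else if (pn == "PM10") {
      out[pn] <- base[[pn]]
    } else {
      stop("no default scaling factor for pollutant ", pn,
           "; supply one via `overrides`")
    }
  }
  stopifnot(all(out > 0))
  out
}

#' Fit the reduced common-trend index model
#'
#' The reduced model drops covariates and spatial components: the scaled
#' concentration y_i(s,t)/F_i loads a latent temporal state through fixed
#' station-specific loadings k_i(s) = (station temporal average of the scaled
#' series) / (network average of the scaled series), which avoids the
#' identifiability problems of estimating the loading matrix. Only G,
#' Sigma_eta and the noise variances are estimated, by the same EM.
#'
#' @param obs a [dcm_observations()] on the original concentration scale
#' @param F named scaling factors (see [default_scaling_factors()])
#' @param p latent dimension: q (each pollutant keeps its own trend, default)
#'   or 1 (single common trend for highly positively correlated pollutants)
#' @param control EM control list (see [em_fit()])
#' @return a `dcm_fit` with `$loadings` (per entry), `$F`, and smoother
#'   output for the index functions
#' @export
build_index_model <- function(obs, F = default_scaling_factors(obs$network$pollutants),
                              p = NULL, control = list()) {
  net <- obs$network
  if (!is.null(obs$transform))
    stop("pass observations on the original concentration scale")
  q <- length(net$pollutants)
  if (is.null(p)) p <- q
  if (!p %in% c(1L, q)) stop("p must be 1 or the number of pollutants")
  pol <- entry_pollutant(net)
  Fv <- F[net$pollutants]
  scaled <- obs$values / Fv[pol]

  drop <- rowSums(!is.na(scaled)) == 0L
  if (any(drop)) {
    warning("excluding ", sum(drop), " station(s) with all-missing series")
    keep <- net$sites[!drop, , drop = FALSE]
    net <- dcm_network(keep, net$pollutants, net$dist_method)
    scaled <- scaled[!drop, , drop = FALSE]
    pol <- entry_pollutant(net)
  }

  sbar <- rowMeans(scaled, na.rm = TRUE)            # station temporal average
  nbar <- vapply(seq_len(q), function(i)
    mean(scaled[pol == i, , drop = FALSE], na.rm = TRUE), numeric(1))
  load <- sbar / nbar[pol]

  H <- matrix(0, length(pol), p)
  if (p == 1L) H[, 1] <- load else H[cbind(seq_along(pol), pol)] <- load

  cfg <- dcm_config(q = q, p = p, pollutants = net$pollutants,
                    K = if (p == 1L) matrix(1, q, 1) else diag(q),
                    include_u = FALSE, include_w = FALSE)
  obs2 <- dcm_observations(net, obs$dates, scaled)
  lvl <- mean(scaled, na.rm = TRUE)
  init <- dcm_parameters(cfg, G = diag(0.5, p),
                         Sigma_eta = diag(max(0.1 * lvl^2, 1e-4), p),
                         sigma2 = rep(max(0.25 * stats::var(as.vector(scaled),
                                                            na.rm = TRUE), 1e-6), q))
  ctl <- modifyList(list(P0 = max(10, 10 * lvl^2)), control)
  fit <- em_fit(obs2, covariates = NULL, config = cfg, init = init, H = H,
                update = c("G", "Sigma_eta", "phi"), control = ctl)
  fit$loadings <- load
  fit$F <- Fv
  fit
}

index_states <- function(x, P = NULL) {
  # accept a dcm_fit (index model) or explicit z (p x T) + P (p x p x T)
  if (inherits(x, "dcm_fit")) {
    Tn <- ncol(x$obs$values)
    z <- x$smoother$z[, 2:(Tn + 1), drop = FALSE]
    P <- x$smoother$P[, , 2:(Tn + 1), drop = FALSE]
    dates <- x$obs$dates
  } else {
    z <- as.matrix(x)
    if (is.null(P)) stop("P required when passing raw states")
    if (length(dim(P)) == 2L) P <- array(P, dim = c(dim(P), 1L))
    dates <- seq_len(ncol(z))
  }
  list(z = z, P = P, dates = dates)
}

#' Global air-quality index I1 (scalar latent state)
#'
#' Requires the single-trend model (p = 1): the index is the smoothed scalar
#' state itself, with Gaussian 95% bounds from its smoothed variance.
#'
#' @param x an index-model `dcm_fit` with p = 1, or a 1 x T state matrix
#' @param P smoothed state variances when raw states are passed
#' @return data.frame: date, value, var, lower, upper
#' @export
index_I1 <- function(x, P = NULL) {
  st <- index_states(x, P)
  if (nrow(st$z) != 1L)
    stop("I1 requires p = 1; use index_I2/index_I3 for multi-trend models")
  v <- st$P[1, 1, ]
  data.frame(date = st$dates, value = st$z[1, ], var = v,
             lower = st$z[1, ] - 1.96 * sqrt(v),
             upper = st$z[1, ] + 1.96 * sqrt(v))
}

#' Global air-quality index I2 (mean of the latent states)
#'
#' I2(t) = mean_i z_i(t), with variance (1/q^2) sum_ij p_ij(t) from the
#' smoothed state covariance and a Gaussian 95% interval.
#'
#' @inheritParams index_I1
#' @return data.frame: date, value, var, lower, upper
#' @export
index_I2 <- function(x, P = NULL) {
  st <- index_states(x, P)
  q <- nrow(st$z)
  val <- colMeans(st$z)
  v <- apply(st$P, 3, sum) / q^2
  data.frame(date = st$dates, value = val, var = v,
             lower = val - 1.96 * sqrt(v),
             upper = val + 1.96 * sqrt(v))
}

#' Global air-quality index I3 (max of the latent states)
#'
#' I3(t) = max_i z_i(t); the maximizing pollutant is recorded per day and the
#' 95% interval comes from Monte-Carlo quantiles of max of N(z(t), P(t))
#' draws (the max of correlated Gaussians has no simple closed form).
#'
#' @inheritParams index_I1
#' @param nsim Monte-Carlo draws per day (>= 100)
#' @param seed RNG seed
#' @param pollutants names for the argmax column
#' @return data.frame: date, value, argmax, lower, upper
#' @export
index_I3 <- function(x, P = NULL, nsim = 10000L, seed = 1L, pollutants = NULL) {
  if (nsim < 100L) stop("nsim must be at least 100")
  st <- index_states(x, P)
  q <- nrow(st$z); Tn <- ncol(st$z)
  if (is.null(pollutants)) {
    pollutants <- if (inherits(x, "dcm_fit")) x$config$pollutants else
      paste0("y", seq_len(q))
  }
  set.seed(seed)
  val <- apply(st$z, 2, max)
  am <- pollutants[apply(st$z, 2, which.max)]
  lo <- hi <- numeric(Tn)
  for (t in seq_len(Tn)) {
    L <- chol_psd(st$P[, , t])
    draws <- st$z[, t] + L %*% matrix(rnorm(q * nsim), q, nsim)
    mx <- apply(draws, 2, max)
    qq <- quantile(mx, c(0.025, 0.975), names = FALSE)
    lo[t] <- qq[1]; hi[t] <- qq[2]
  }
  data.frame(date = st$dates, value = val, argmax = am, lower = lo, upper = hi)
}
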