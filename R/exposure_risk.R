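# Population exposure and exceedance risk: exposure indices and cumulative
# exposure distribution, the residual-CDF exceedance-probability procedure,
# Poisson-binomial day counts and parametric-bootstrap confidence bands.

check_grid_alignment <- function(values, grid, cells) {
  if (is.null(cells)) cells <- which(grid$mask)
  if (NROW(values) != length(cells))
    stop("grid mismatch: values and population are not on the same cells")
  cells
}

#' Population exposure index
#'
#' Couples the temporally averaged concentration field with the population
#' raster: the block index is d(B) * ybar(B) / D (so block indices sum to the
#' region average) and the region average exposure is the population-weighted
#' mean sum_B d(B) ybar(B) / D. Zero-population blocks carry zero weight.
#'
#' @param values per-cell average concentrations (original scale), aligned
#'   with the masked cells of `grid` (or with `cells`)
#' @param grid a [dcm_grid()] with population counts
#' @param cells optional cell indices the values refer to
#' @return list: `block` (per-cell index), `region` (average exposure),
#'   `population` (weights used), `D` (total population)
#' @export
exposure_index <- function(values, grid, cells = NULL) {
  cells <- check_grid_alignment(values, grid, cells)
  d <- grid$population[cells]
  D <- sum(d)
  if (D <= 0) stop("total population is zero")
  ok <- is.finite(values)
  region <- sum(d[ok] * values[ok]) / sum(d[ok])
  list(block = d * values / D, region = region, population = d, D = D)
}

#' Cumulative exposure distribution
#'
#' Phi(c) = sum_B d(B) 1{ybar(B) <= c} / D: the population fraction exposed
#' to an average concentration at or below c (non-decreasing,
#' right-continuous step function with limits 0 and 1), plus a
#' Gaussian-kernel-smoothed exposure density for display.
#'
#' @inheritParams exposure_index
#' @param bandwidth Gaussian kernel bandwidth for the density (ug/m3),
#'   default 0.5
#' @return list: `cdf` (callable step function), `density` (callable),
#'   `support` (sorted concentrations), `weights`, `mean`
#' @export
cumulative_exposure <- function(values, grid, cells = NULL, bandwidth = 0.5) {
  cells <- check_grid_alignment(values, grid, cells)
  d <- grid$population[cells]
  ok <- is.finite(values)
  values <- values[ok]; d <- d[ok]
  D <- sum(d)
  if (D <= 0) stop("total population is zero")
  o <- order(values)
  v <- values[o]; w <- d[o] / D
  cw <- cumsum(w)
  cdf <- function(c) vapply(c, function(ci) {
    i <- findInterval(ci, v)
    if (i == 0) 0 else cw[i]
  }, numeric(1))
  dens <- function(c) vapply(c, function(ci)
    sum(w * dnorm(ci - v, sd = bandwidth)), numeric(1))
  list(cdf = cdf, density = dens, support = v, weights = w,
       mean = sum(w * v), bandwidth = bandwidth)
}

#' Daily population counts above threshold
#'
#' Number of people living in blocks whose predicted concentration exceeds
#' the threshold, per day: count_t = sum_B d(B) 1{yhat(B,t) > L}.
#'
#' @param values cells x days matrix of predicted concentrations (original
#'   scale)
#' @param grid a [dcm_grid()]
#' @param L threshold on the original concentration scale
#' @param cells optional cell indices
#' @return numeric vector per day
#' @export
daily_exceedance_population <- function(values, grid, L, cells = NULL) {
  values <- as.matrix(values)
  cells <- check_grid_alignment(values, grid, cells)
  d <- grid$population[cells]
  as.vector(crossprod(values > L, d))
}

#' Kernel-smoothed CDF of the Studentized cross-validation residuals
#'
#' Pools the Studentized leave-one-site-out residuals and smooths their
#' empirical distribution with a Gaussian kernel: F(x) = mean Phi((x - r_i)/h).
#' The returned object evaluates the CDF at arbitrary points (a fine
#' interpolation grid keeps evaluation over full maps cheap).
#'
#' @param residuals numeric vector of pooled Studentized residuals, or a
#'   `dcm_crossval` from [loso_crossval()]
#' @param bandwidth kernel bandwidth; default Silverman's rule
#' @return `dcm_residual_cdf`; evaluate with [eval_residual_cdf()]
#' @export
fit_residual_cdf <- function(residuals, bandwidth = NULL) {
  if (inherits(residuals, "dcm_crossval")) residuals <- residuals$pooled
  residuals <- residuals[is.finite(residuals)]
  n <- length(residuals)
  if (n < 50) stop("need at least 50 pooled residuals, got ", n)
  if (is.null(bandwidth))
    bandwidth <- 0.9 * min(sd(residuals), IQR_safe(residuals) / 1.34) * n^(-1/5)
  lo <- min(residuals) - 8 * bandwidth
  hi <- max(residuals) + 8 * bandwidth
  gx <- seq(lo, hi, length.out = 4001L)
  gy <- vapply(gx, function(x) mean(pnorm((x - residuals) / bandwidth)), numeric(1))
  fast <- approxfun(gx, gy, yleft = 0, yright = 1)
  structure(list(residuals = residuals, bandwidth = bandwidth,
                 grid_x = gx, fast = fast, n = n),
            class = "dcm_residual_cdf")
}

IQR_safe <- function(x) {
  r <- diff(quantile(x, c(0.25, 0.75), names = FALSE))
  if (r <= 0) sd(x) else r
}

#' Evaluate a smoothed residual CDF
#' @param rcdf a `dcm_residual_cdf`
#' @param x evaluation points
#' @param exact use the exact kernel sum instead of the interpolation grid
#' @return CDF values in [0, 1]
#' @export
eval_residual_cdf <- function(rcdf, x, exact = FALSE) {
  if (exact) {
    vapply(x, function(xi)
      mean(pnorm((xi - rcdf$residuals) / rcdf$bandwidth)), numeric(1))
  } else {
    pmin(1, pmax(0, rcdf$fast(x)))
  }
}

#' Exceedance probability surface
#'
#' pi(B,t) = 1 - F((L_tilde - yhat(B,t)) / sigma(B,t)), with the threshold
#' mapped to the transformed model scale, the kriging mean/sd on the model
#' scale and F the smoothed Studentized-residual CDF. Cells with zero
#' kriging sd get the direct indicator.
#'
#' @param map a `dcm_map` from [krige()]
#' @param L threshold on the original concentration scale
#' @param rcdf a `dcm_residual_cdf`; `NULL` uses the standard normal CDF
#' @param transform transform record mapping L to the model scale; default
#'   the map's record
#' @return cells x days matrix of probabilities in [0, 1]
#' @export
exceedance_probability <- function(map, L, rcdf = NULL, transform = NULL) {
  if (is.null(transform)) transform <- map$transform
  Lt <- if (is.null(transform)) L else apply_transform(L, transform, map$pollutant)
  z <- (Lt - map$yhat) / map$sd
  pi <- if (is.null(rcdf)) 1 - pnorm(z) else 1 - eval_residual_cdf(rcdf, z)
  pi <- matrix(pi, nrow(map$yhat), ncol(map$yhat))
  zero <- map$sd == 0
  if (any(zero)) pi[zero] <- as.numeric(map$yhat[zero] > Lt)
  pi
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of N = sum_t Bernoulli(pi_t) (independent, unequal
#' probabilities) by the dynamic-programming convolution.
#'
#' @param pi vector of daily probabilities in [0, 1]
#' @return pmf over 0..length(pi)
#' @export
poisbinom_pmf <- function(pi) {
  stopifnot(all(pi >= 0 & pi <= 1))
  f <- 1
  for (p in pi) f <- c(f, 0) * (1 - p) + c(0, f) * p
  f
}

#' Distribution of the number of exceedance days
#'
#' N = sum over days of Bernoulli(pi_t), with independence across days (an
#' approximation: the concentration field is temporally correlated, so the
#' true day counts are over-dispersed relative to this law). Exact mode uses
#' the Poisson-binomial convolution; Monte-Carlo mode simulates seeded runs.
#'
#' @param pi daily exceedance probabilities for one block
#' @param M day-count limit (P(N > M) is reported)
#' @param method `"exact"` or `"montecarlo"`
#' @param nsim Monte-Carlo runs (default 500)
#' @param seed RNG seed for Monte-Carlo mode
#' @return list: `pmf` (over 0..T; relative frequencies for Monte Carlo),
#'   `mean`, `p_gt_M`
#' @export
day_count_distribution <- function(pi, M = 7L, method = c("exact", "montecarlo"),
                                   nsim = 500L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(all(pi >= 0 & pi <= 1))
  Tn <- length(pi)
  if (method == "exact") {
    pmf <- poisbinom_pmf(pi)
  } else {
    set.seed(seed)
    N <- colSums(matrix(runif(Tn * nsim), Tn, nsim) < pi)
    pmf <- tabulate(N + 1L, nbins = Tn + 1L) / nsim
  }
  p_gt <- if (M >= Tn) 0 else sum(pmf[seq(M + 2L, Tn + 1L)])
  list(pmf = pmf, mean = sum(seq(0, Tn) * pmf), p_gt_M = p_gt)
}

#' Per-block day-count risk summaries
#'
#' Applies [day_count_distribution()] to every row of an exceedance
#' probability surface.
#'
#' @param pi_surface cells x days matrix from [exceedance_probability()]
#' @param M day-count limit
#' @param method,nsim,seed passed to [day_count_distribution()]
#' @return data.frame: `mean_days`, `p_gt_M` per cell
#' @export
risk_day_counts <- function(pi_surface, M = 7L, method = c("exact", "montecarlo"),
                            nsim = 500L, seed = 1L) {
  method <- match.arg(method)
  out <- t(vapply(seq_len(nrow(pi_surface)), function(b) {
    d <- day_count_distribution(pi_surface[b, ], M = M, method = method,
                                nsim = nsim, seed = seed + b)
    c(d$mean, d$p_gt_M)
  }, numeric(2)))
  data.frame(mean_days = out[, 1], p_gt_M = out[, 2])
}

#' Aggregated daily risk index
#'
#' Country-level daily risk: the population-weighted (default) or unweighted
#' mean of the block exceedance probabilities.
#'
#' @param pi_surface cells x days matrix
#' @param grid a [dcm_grid()]
#' @param cells optional cell indices
#' @param weights `"population"` or `"uniform"`
#' @return numeric vector per day
#' @export
aggregated_risk_series <- function(pi_surface, grid, cells = NULL,
                                   weights = c("population", "uniform")) {
  weights <- match.arg(weights)
  cells <- check_grid_alignment(pi_surface, grid, cells)
  w <- if (weights == "population") grid$population[cells] else
    rep(1, length(cells))
  as.vector(crossprod(pi_surface, w)) / sum(w)
}

#' Parametric-bootstrap confidence bands
#'
#' Samples R parameter sets from the asymptotic normal distribution of the
#' estimate (on the unconstrained reparameterization, so variances, ranges
#' and correlation matrices map back to valid values), re-evaluates a
#' user-supplied statistic per replicate, and returns pointwise quantile
#' bands. Replicates violating hard constraints (e.g. an unstable G) are
#' redrawn and counted.
#'
#' @param fit a [em_fit()] result
#' @param statistic function `psi -> numeric vector` (the pipeline to band:
#'   exceedance surfaces, day-count maps, aggregated series, ...)
#' @param R bootstrap replications (default 100)
#' @param seed RNG seed
#' @param fisher optional precomputed [fisher_information()]; computed with
#'   its default blocks otherwise
#' @param probs band quantiles (default 2.5% / 97.5%)
#' @return list: `point`, `lower`, `upper`, `draws` (R x length matrix),
#'   `n_redraw`
#' @export
bootstrap_bands <- function(fit, statistic, R = 100L, seed = 1L,
                            fisher = NULL, probs = c(0.025, 0.975)) {
  if (is.null(fisher)) fisher <- fisher_information(fit)
  set.seed(seed)
  x0 <- fisher$par
  Lc <- chol_psd(fisher$vcov)
  point <- statistic(fit$psi)
  draws <- matrix(NA_real_, R, length(point))
  n_redraw <- 0L
  for (j in seq_len(R)) {
    ok <- FALSE
    for (tries in 1:50) {
      x <- x0 + as.vector(Lc %*% rnorm(length(x0)))
      ps <- tryCatch(psi_unflatten(x, fit$psi, fisher$blocks),
                     error = function(e) NULL)
      if (!is.null(ps) && spectral_radius(ps$G) < 1) {
        ps2 <- tryCatch(validate_parameters(ps), error = function(e) NULL)
        if (!is.null(ps2)) { ok <- TRUE; break }
      }
      n_redraw <- n_redraw + 1L
    }
    if (!ok) stop("could not draw a valid bootstrap parameter set")
    draws[j, ] <- statistic(ps)
  }
  qs <- apply(draws, 2, quantile, probs = probs, na.rm = TRUE)
  list(point = point, lower = qs[1, ], upper = qs[2, ], draws = draws,
       n_redraw = n_redraw)
}
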