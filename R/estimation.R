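# Maximum-likelihood estimation: Kalman smoothing with per-day missing-data
# patterns, EM fitting of the full parameter set, Fisher-information standard
# errors and leave-one-site-out cross-validation.

#' Kalman smoother for the state-space form of the model
#'
#' Builds, per day, the measurement equation over the observed entries only
#' (the daily observation-noise covariance marginalizes the spatial
#' components u and w together with the measurement error) and runs the exact
#' fixed-interval smoother. Days with no observations propagate the prior.
#'
#' @param obs a [dcm_observations()]
#' @param covariates a [dcm_covariates()] or `NULL`
#' @param psi a [dcm_parameters()]
#' @param H optional N x p per-entry loading matrix overriding `K[pollutant,]`
#'   (used by the reduced index model, whose loadings are station specific)
#' @param init `"stationary"` (prior solves the discrete Lyapunov equation)
#'   or `"fixed"` (N(0, P0_scale I), used inside EM so the prior does not
#'   depend on the estimated transition)
#' @param P0_scale prior variance scale for `init = "fixed"`
#' @return `dcm_smoother` list: `z` (p x (T+1), state 0 first), `P`
#'   (p x p x (T+1)), `Plag` (Cov(z_t, z_{t-1} | Y), slices t = 1..T) and the
#'   marginal `loglik`
#' @export
kalman_smooth <- function(obs, covariates = NULL, psi, H = NULL,
                          init = c("stationary", "fixed"), P0_scale = 10) {
  init <- match.arg(init)
  validate_parameters(psi)
  net <- obs$network
  pol <- entry_pollutant(net)
  cfg <- psi$config
  if (is.null(H)) H <- entry_loadings(cfg, pol)
  mu <- if (is.null(psi$beta)) matrix(0, nrow(obs$values), ncol(obs$values)) else
    build_mean(psi, covariates, pol)
  Sigma <- residual_covariance(psi, net)
  P0 <- if (init == "stationary") stationary_covariance(psi$G, psi$Sigma_eta) else
    diag(P0_scale, cfg$p)
  out <- cpp_kalman_smoother(obs$values, mu, H, Sigma, psi$G, psi$Sigma_eta,
                             rep(0, cfg$p), P0)
  structure(list(z = out$z, P = out$P, Plag = out$Plag, loglik = out$loglik,
                 init = init), class = "dcm_smoother")
}

# Marginal log-likelihood at psi via the Kalman filter (stationary prior)
kalman_loglik <- function(obs, covariates, psi, H = NULL) {
  kalman_smooth(obs, covariates, psi, H = H, init = "stationary")$loglik
}

default_init <- function(obs, covariates, config, H, seed_jitter = NULL) {
  net <- obs$network
  pol <- entry_pollutant(net)
  q <- config$q
  Y <- obs$values
  beta <- NULL
  resid <- Y
  if (!is.null(covariates)) {
    k <- dim(covariates$station)[2]
    X <- build_design(covariates, q, pol)
    A <- matrix(0, k * q, k * q); b <- numeric(k * q)
    for (t in seq_len(ncol(Y))) {
      idx <- which(!is.na(Y[, t]))
      if (!length(idx)) next
      Xt <- X[idx, , t, drop = FALSE]; dim(Xt) <- c(length(idx), k * q)
      A <- A + crossprod(Xt); b <- b + crossprod(Xt, Y[idx, t])
    }
    beta <- matrix(solve(A + diag(1e-8, k * q), b), k, q)
    Bent <- t(beta)[pol, , drop = FALSE]
    for (t in seq_len(ncol(Y)))
      resid[, t] <- Y[, t] - rowSums(covariates$station[, , t, drop = TRUE] * Bent)
  }
  rv <- vapply(seq_len(q), function(i)
    stats::var(as.vector(resid[pol == i, , drop = FALSE]), na.rm = TRUE), numeric(1))
  rv[!is.finite(rv) | rv < 1e-6] <- 1
  n_spatial <- (config$include_u + config$include_w)
  spatial_share <- if (n_spatial > 0) 0.5 / n_spatial else 0
  D <- network_distances(net)
  med_d <- stats::median(D[upper.tri(D)])
  if (!is.finite(med_d) || med_d <= 1) med_d <- 50
  psi <- structure(list(
    beta = beta, G = diag(0.5, config$p),
    Sigma_eta = diag(0.1 * mean(rv), config$p),
    alpha = if (config$include_u) sqrt(spatial_share * rv),
    theta = if (config$include_u) rep(med_d, q),
    lambda = if (config$include_w) sqrt(spatial_share * rv),
    V = if (config$include_w)
      replicate(config$n_lcm, 0.7 * diag(q) + 0.3, simplify = FALSE),
    theta_tilde = if (config$include_w) rep(med_d, config$n_lcm),
    sigma2 = 0.5 * rv, config = config), class = "dcm_parameters")
  if (!is.null(seed_jitter)) {
    set.seed(seed_jitter)
    x <- phi_pack(psi)
    psi <- phi_unpack(x + rnorm(length(x), 0, 0.1), psi)
  }
  validate_parameters(psi)
  psi
}

#' Fit the dynamic coregionalization model by EM
#'
#' Expectation-conditional-maximization: the E-step runs the Kalman smoother
#' with the spatial components marginalized into the daily observation-noise
#' covariance; the M-step updates beta (GLS), G and Sigma_eta (closed form
#' from the smoothed second moments) and the covariance parameters
#' (alpha, theta, lambda, V, theta_tilde, sigma2) by a bounded, warm-started
#' quasi-Newton maximization of the expected complete-data log-likelihood on
#' an unconstrained reparameterization. Every step increases the marginal
#' likelihood, so the trace is monotone up to numerical slack.
#'
#' @param obs a [dcm_observations()]
#' @param covariates a [dcm_covariates()] or `NULL` (then no beta)
#' @param config a [dcm_config()]
#' @param init optional initial [dcm_parameters()]; default data-driven
#'   (OLS beta, 50/50 spatial/noise variance split, G = 0.5 I, ranges at the
#'   median inter-station distance)
#' @param H optional per-entry loading override (reduced index model)
#' @param update parameter blocks to update; default all present
#' @param control list: `tol` (relative log-likelihood change, default 1e-5),
#'   `maxit` (default 400), `phi_maxit` (inner quasi-Newton iterations,
#'   default 10), `P0` (fixed prior variance scale, default 10),
#'   `var_floor` (default 1e-10), `verbose`
#' @return `dcm_fit` with the estimate `psi`, the log-likelihood `trace`,
#'   convergence status, the final stationary-prior smoother output and the
#'   stationary-prior log-likelihood
#' @export
em_fit <- function(obs, covariates = NULL, config, init = NULL, H = NULL,
                   update = c("beta", "G", "Sigma_eta", "phi"),
                   control = list()) {
  ctl <- modifyList(list(tol = 1e-5, maxit = 400, phi_maxit = 10, P0 = 10,
                         var_floor = 1e-10, verbose = FALSE), control)
  net <- obs$network
  pol <- entry_pollutant(net)
  q <- config$q; p <- config$p
  if (is.null(H)) H <- entry_loadings(config, pol)
  psi <- if (is.null(init)) default_init(obs, covariates, config, H) else init
  if (is.null(covariates)) update <- setdiff(update, "beta")
  Y <- obs$values
  Tn <- ncol(Y)
  D <- network_distances(net)
  X <- if ("beta" %in% update) build_design(covariates, q, pol) else NULL
  bounds <- phi_bounds(config)
  floored <- FALSE

  trace <- numeric(0)
  converged <- FALSE
  a0 <- rep(0, p); P0 <- diag(ctl$P0, p)
  for (it in seq_len(ctl$maxit)) {
    Sigma <- spatial_covariance_matrix(psi, D, pol, noise = TRUE)
    mu <- if (is.null(psi$beta)) matrix(0, nrow(Y), Tn) else
      build_mean(psi, covariates, pol)
    sm <- cpp_kalman_smoother(Y, mu, H, Sigma, psi$G, psi$Sigma_eta, a0, P0)
    trace <- c(trace, sm$loglik)
    if (ctl$verbose) message(sprintf("EM iter %d: loglik %.6f", it, sm$loglik))
    if (it > 1) {
      dll <- trace[it] - trace[it - 1]
      if (abs(dll) < ctl$tol * (abs(trace[it - 1]) + 1)) { converged <- TRUE; break }
    }
    Z1 <- sm$z[, 2:(Tn + 1), drop = FALSE]
    Z0 <- sm$z[, 1:Tn, drop = FALSE]
    Psum1 <- apply(sm$P[, , 2:(Tn + 1), drop = FALSE], c(1, 2), sum)
    Psum0 <- apply(sm$P[, , 1:Tn, drop = FALSE], c(1, 2), sum)
    Plsum <- apply(sm$Plag, c(1, 2), sum)
    S11 <- Z1 %*% t(Z1) + Psum1
    S00 <- Z0 %*% t(Z0) + Psum0
    S10 <- Z1 %*% t(Z0) + Plsum

    if ("G" %in% update) {
      Gnew <- S10 %*% solve(sym(S00) + diag(1e-10, p))
      sr <- spectral_radius(Gnew)
      if (sr >= 0.999) Gnew <- Gnew * (0.995 / sr)
      psi$G <- Gnew
    }
    if ("Sigma_eta" %in% update) {
      Se <- (S11 - psi$G %*% t(S10) - S10 %*% t(psi$G) +
               psi$G %*% S00 %*% t(psi$G)) / Tn
      ev <- eigen(sym(Se), symmetric = TRUE)
      if (min(ev$values) < ctl$var_floor) {
        floored <- TRUE
        ev$values <- pmax(ev$values, ctl$var_floor)
        Se <- ev$vectors %*% diag(ev$values, p) %*% t(ev$vectors)
      }
      psi$Sigma_eta <- sym(Se)
    }
    if ("beta" %in% update) {
      R <- Y - H %*% Z1
      gls <- cpp_beta_gls(R, X, Sigma)
      k <- dim(covariates$station)[2]
      psi$beta <- matrix(solve(gls$A + diag(1e-10, k * q), gls$b), k, q,
                         dimnames = list(covariates$names, config$pollutants))
      mu <- build_mean(psi, covariates, pol)
    }
    if ("phi" %in% update) {
      E <- Y - mu - H %*% Z1
      P_slices <- sm$P
      Sig_of <- function(x)
        spatial_covariance_matrix(phi_unpack(x, psi), D, pol, noise = TRUE)
      cache <- new.env(parent = emptyenv())
      qw_at <- function(x) {
        key <- paste(format(x, digits = 17), collapse = ",")
        if (identical(cache$key, key)) return(cache$val)
        val <- cpp_gauss_Q_grad(E, H, P_slices, Sig_of(x))
        cache$key <- key; cache$val <- val
        val
      }
      negQ <- function(x) {
        v <- qw_at(x)$Q
        if (!is.finite(v)) 1e12 else v
      }
      # dQ/dx_k = accu(W % dSigma/dx_k); Sigma is cheap to rebuild, so the
      # directional derivatives come from central differences on Sigma only
      gradQ <- function(x) {
        W <- qw_at(x)$W
        h <- 1e-6
        vapply(seq_along(x), function(k) {
          xp <- x; xp[k] <- xp[k] + h
          xm <- x; xm[k] <- xm[k] - h
          sum(W * (Sig_of(xp) - Sig_of(xm))) / (2 * h)
        }, numeric(1))
      }
      x0 <- phi_pack(psi)
      q0 <- negQ(x0)
      opt <- tryCatch(
        optim(x0, negQ, gradQ, method = "L-BFGS-B",
              lower = bounds$lower, upper = bounds$upper,
              control = list(maxit = ctl$phi_maxit)),
        error = function(e) list(par = x0, value = q0))
      if (is.finite(opt$value) && opt$value <= q0 + 1e-9)
        psi <- phi_unpack(opt$par, psi)
      if (any(psi$sigma2 < 1e-8)) {
        floored <- TRUE
        psi$sigma2 <- pmax(psi$sigma2, 1e-8)
      }
    }
  }
  if (!converged)
    warning("EM did not converge in ", ctl$maxit,
            " iterations; returning best iterate")
  if (floored)
    warning("degenerate variance collapse detected; floored at lower bound")
  sm_final <- kalman_smooth(obs, covariates, psi, H = H, init = "stationary")
  structure(list(psi = psi, config = config, trace = trace,
                 converged = converged, iterations = length(trace),
                 loglik = sm_final$loglik, smoother = sm_final,
                 obs = obs, covariates = covariates, H = H,
                 control = ctl),
            class = "dcm_fit")
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat("dcm_fit:", x$iterations, "EM iterations,",
      if (x$converged) "converged," else "NOT converged,",
      sprintf("loglik %.3f", x$loglik), "\n")
  invisible(x)
}

pseudo_inverse <- function(A, tol = 1e-10) {
  e <- eigen(sym(A), symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  e$vectors[, pos, drop = FALSE] %*%
    diag(1 / e$values[pos], sum(pos)) %*% t(e$vectors[, pos, drop = FALSE])
}

#' Approximate Fisher information at the estimate
#'
#' Numerical negative Hessian of the marginal (Kalman) log-likelihood at
#' psi-hat, by central differences with a per-parameter relative step, on the
#' natural scale for beta and G and on the unconstrained scale for the
#' covariance parameters. Standard deviations come from the inverse diagonal;
#' a non-invertible information falls back to the pseudo-inverse with a
#' warning. For Gaussian models the mean parameters (beta) are asymptotically
#' orthogonal to the covariance parameters, so `blocks = "beta"` gives valid
#' beta standard errors at a fraction of the cost.
#'
#' @param fit a [em_fit()] result
#' @param blocks parameter blocks to differentiate
#' @param rel_step relative step size (default 1e-4)
#' @return `dcm_fisher` list: `information`, `vcov`, `sd` (named), `par`
#' @export
fisher_information <- function(fit, blocks = c("beta", "G", "Sigma_eta", "phi"),
                               rel_step = 1e-4) {
  psi <- fit$psi
  blocks <- intersect(blocks, c("beta", "G", "Sigma_eta", "phi"))
  if (is.null(psi$beta)) blocks <- setdiff(blocks, "beta")
  x0 <- psi_flatten(psi, blocks)
  d <- length(x0)
  nll <- function(x) {
    ps <- tryCatch(psi_unflatten(x, psi, blocks), error = function(e) NULL)
    if (is.null(ps) || spectral_radius(ps$G) >= 1) return(NA_real_)
    ll <- tryCatch(kalman_loglik(fit$obs, fit$covariates, ps, H = fit$H),
                   error = function(e) NA_real_)
    -ll
  }
  h <- rel_step * (abs(x0) + 0.01)
  f0 <- nll(x0)
  Hm <- matrix(NA_real_, d, d)
  fp <- fm <- numeric(d)
  for (i in seq_len(d)) {
    ei <- rep(0, d); ei[i] <- h[i]
    fp[i] <- nll(x0 + ei); fm[i] <- nll(x0 - ei)
    Hm[i, i] <- (fp[i] - 2 * f0 + fm[i]) / h[i]^2
  }
  if (d > 1) for (i in 1:(d - 1)) for (j in (i + 1):d) {
    ei <- rep(0, d); ei[i] <- h[i]
    ej <- rep(0, d); ej[j] <- h[j]
    Hm[i, j] <- Hm[j, i] <-
      (nll(x0 + ei + ej) - nll(x0 + ei - ej) -
         nll(x0 - ei + ej) + nll(x0 - ei - ej)) / (4 * h[i] * h[j])
  }
  Hm <- sym(Hm)
  vcov <- tryCatch(solve(Hm), error = function(e) NULL)
  if (is.null(vcov) || any(!is.finite(vcov)) || any(diag(vcov) < 0)) {
    warning("information matrix not invertible; using pseudo-inverse")
    vcov <- pseudo_inverse(Hm)
  }
  sdv <- sqrt(pmax(diag(vcov), 0))
  names(sdv) <- names(x0)
  structure(list(information = Hm, vcov = vcov, sd = sdv, par = x0,
                 blocks = blocks), class = "dcm_fisher")
}

#' Leave-one-site-out cross-validation
#'
#' For each station, predictions at that station use all data except the
#' station's own series (the parameter estimate is not re-computed by
#' default; set `re_estimate = TRUE` to re-run EM per held-out station).
#' Residuals are Studentized by the dynamic kriging standard deviation.
#' Entries sharing a station id across pollutants are held out together.
#'
#' @param fit a [em_fit()] result
#' @param re_estimate re-run EM without each held-out station (slow)
#' @return `dcm_crossval` list: `residuals`, `sd`, `studentized` (N x T, on
#'   the transformed scale), pooled Studentized residual vector, per-pollutant
#'   cross-validation mean-squared error `cmse` and in-sample `insample_mse`,
#'   and the names of single-station pollutants (predictions there rely on
#'   cross-pollutant information only)
#' @export
loso_crossval <- function(fit, re_estimate = FALSE) {
  obs <- fit$obs; net <- obs$network
  psi <- fit$psi; cfg <- fit$config
  pol <- entry_pollutant(net)
  Y <- obs$values; Tn <- ncol(Y)
  D <- network_distances(net)
  H <- if (is.null(fit$H)) entry_loadings(cfg, pol) else fit$H
  mu <- if (is.null(psi$beta)) matrix(0, nrow(Y), Tn) else
    build_mean(psi, fit$covariates, pol)
  Sigma_full <- spatial_covariance_matrix(psi, D, pol, noise = TRUE)
  Sigma_nonugget <- spatial_covariance_matrix(psi, D, pol, noise = FALSE)
  c0_all <- prior_spatial_variance(psi, pol)

  pred <- sdm <- matrix(NA_real_, nrow(Y), Tn)
  stations <- unique(net$sites$station)
  for (st in stations) {
    e <- which(net$sites$station == st)
    psi_s <- psi
    if (re_estimate) {
      obs_minus <- obs; obs_minus$values[e, ] <- NA
      psi_s <- em_fit(obs_minus, fit$covariates, cfg, init = psi, H = fit$H,
                      control = modifyList(fit$control, list(maxit = 50)))$psi
    }
    Ym <- Y; Ym[e, ] <- NA
    Sg <- spatial_covariance_matrix(psi_s, D, pol, noise = TRUE)
    mus <- if (is.null(psi_s$beta)) mu else build_mean(psi_s, fit$covariates, pol)
    sm <- cpp_kalman_smoother(Ym, mus, H, Sg, psi_s$G, psi_s$Sigma_eta,
                              rep(0, cfg$p),
                              stationary_covariance(psi_s$G, psi_s$Sigma_eta))
    Z1 <- sm$z[, 2:(Tn + 1), drop = FALSE]
    E <- Ym - mus - H %*% Z1
    kr <- cpp_krige(E, H, Sg,
                    spatial_covariance_matrix(psi_s, D, pol, noise = FALSE)[e, , drop = FALSE],
                    prior_spatial_variance(psi_s, pol[e]),
                    H[e, , drop = FALSE], sm$P)
    pred[e, ] <- mus[e, , drop = FALSE] + H[e, , drop = FALSE] %*% Z1 + kr$adj
    # predictive sd of the held-out OBSERVATION: kriging variance of the
    # concentration plus the measurement-error variance, so that pooled
    # Studentized residuals are approximately standard
    sdm[e, ] <- sqrt(kr$var + psi_s$sigma2[pol[e]])
  }
  resid <- Y - pred
  stud <- resid / sdm
  stud[!is.finite(stud)] <- NA

  # in-sample counterpart: same prediction machinery with nothing held out
  sm <- kalman_smooth(obs, fit$covariates, psi, H = fit$H, init = "stationary")
  Z1 <- sm$z[, 2:(Tn + 1), drop = FALSE]
  E <- Y - mu - H %*% Z1
  kr <- cpp_krige(E, H, Sigma_full, Sigma_nonugget, c0_all, H, sm$P)
  resid_in <- Y - (mu + H %*% Z1 + kr$adj)

  cmse <- vapply(seq_len(cfg$q), function(i)
    mean(resid[pol == i, , drop = FALSE]^2, na.rm = TRUE), numeric(1))
  imse <- vapply(seq_len(cfg$q), function(i)
    mean(resid_in[pol == i, , drop = FALSE]^2, na.rm = TRUE), numeric(1))
  names(cmse) <- names(imse) <- cfg$pollutants
  single <- cfg$pollutants[station_counts(net) == 1L]
  structure(list(residuals = resid, sd = sdm, studentized = stud,
                 pooled = stud[!is.na(stud)],
                 cmse = cmse, insample_mse = imse,
                 single_station_pollutants = single),
            class = "dcm_crossval")
}
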