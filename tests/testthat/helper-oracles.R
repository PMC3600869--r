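# Shared fixtures and independent brute-force oracles. The oracles condition
# the dense joint Gaussian of the full observation stack directly and never
# touch the Kalman recursion or the per-day kriging solves they check.

# plug-in fit object around a known parameter set (no estimation)
plugin_fit <- function(psi, obs, covariates = NULL, H = NULL) {
  sm <- kalman_smooth(obs, covariates, psi, H = H, init = "stationary")
  structure(list(psi = psi, config = psi$config, obs = obs,
                 covariates = covariates, smoother = sm, H = H,
                 control = list()), class = "dcm_fit")
}

# dense conditional of the stacked latent state given the observed data:
# E[z | Y] and Cov(z | Y) per day, from the full joint covariance
oracle_smoother <- function(psi, obs, covariates = NULL) {
  net <- obs$network
  Tn <- ncol(obs$values)
  p <- psi$config$p
  pol <- dcmair:::entry_pollutant(net)
  jm <- dcmair:::dense_joint_model(psi, net, Tn)
  mu <- if (is.null(psi$beta)) 0 * obs$values else
    dcmair:::build_mean(psi, covariates, pol)
  y <- as.vector(obs$values); m <- as.vector(mu)
  keep <- !is.na(y)
  S <- jm$Sy[keep, keep, drop = FALSE]
  r <- y[keep] - m[keep]
  Czy <- jm$Sz %*% t(jm$Hbig[keep, , drop = FALSE])
  zhat <- matrix(Czy %*% solve(S, r), p, Tn)
  Pz <- jm$Sz - Czy %*% solve(S, t(Czy))
  P <- array(NA_real_, dim = c(p, p, Tn))
  for (t in seq_len(Tn))
    P[, , t] <- Pz[((t - 1) * p + 1):(t * p), ((t - 1) * p + 1):(t * p)]
  list(z = zhat, P = P)
}

# dense conditional mean / sd of the noise-free concentration of pollutant
# `pol0` at a new site, per day (the quantity dynamic kriging estimates)
oracle_krige <- function(psi, obs, covariates, lon0, lat0, pol0, mu0) {
  net <- obs$network
  Tn <- ncol(obs$values)
  pol <- dcmair:::entry_pollutant(net)
  N <- length(pol)
  jm <- dcmair:::dense_joint_model(psi, net, Tn)
  mu <- if (is.null(psi$beta)) 0 * obs$values else
    dcmair:::build_mean(psi, covariates, pol)
  y <- as.vector(obs$values); m <- as.vector(mu)
  keep <- !is.na(y)
  S <- jm$Sy[keep, keep, drop = FALSE]
  r <- y[keep] - m[keep]
  K0 <- psi$config$K[pol0, , drop = FALSE]
  Dc <- dcmair:::cross_distances(net, lon0, lat0)
  csp <- dcmair:::cross_spatial_covariance(psi, Dc, pol0, pol)
  v0 <- dcmair:::prior_spatial_variance(psi, pol0)
  p <- psi$config$p
  mean_out <- sd_out <- numeric(Tn)
  for (t in seq_len(Tn)) {
    zblk <- ((t - 1) * p + 1):(t * p)
    Cy <- K0 %*% jm$Sz[zblk, , drop = FALSE] %*% t(jm$Hbig)
    day <- ((t - 1) * N + 1):(t * N)
    Cy[1, day] <- Cy[1, day] + csp
    Cy <- Cy[, keep, drop = FALSE]
    mean_out[t] <- mu0[t] + Cy %*% solve(S, r)
    vv <- K0 %*% jm$Sz[zblk, zblk] %*% t(K0) + v0 - Cy %*% solve(S, t(Cy))
    sd_out[t] <- sqrt(max(0, vv))
  }
  list(mean = mean_out, sd = sd_out)
}

# small random parameter set for fuzz tests
random_psi <- function(q = 2, include_u = TRUE, include_w = TRUE, k = 0) {
  cfg <- dcm_config(q = q, p = q, pollutants = paste0("P", 1:q),
                    include_u = include_u, include_w = include_w, n_lcm = 1)
  A <- matrix(runif(q * q, -0.5, 0.5), q)
  V <- stats::cov2cor(crossprod(A) + diag(q))
  dcm_parameters(cfg,
                 beta = if (k > 0) matrix(rnorm(k * q, 0, 0.3), k, q),
                 G = diag(runif(q, -0.6, 0.8), q),
                 Sigma_eta = diag(runif(q, 0.01, 0.2), q),
                 alpha = if (include_u) runif(q, 0.2, 1),
                 theta = if (include_u) runif(q, 20, 120),
                 lambda = if (include_w) runif(q, 0.2, 1),
                 V = if (include_w) list(V),
                 theta_tilde = if (include_w) runif(1, 20, 120),
                 sigma2 = runif(q, 0.05, 0.4))
}
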