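# Generative side of the model: simulation of observation sets from a known
# parameter set, and the exact (dense joint-Gaussian) log-likelihood used as
# the independent route against the Kalman-based evaluation.

chol_psd <- function(S) {
  # Cholesky-like factor tolerant of semi-definiteness
  out <- tryCatch(t(chol(sym(S))), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(sym(S), symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(v), length(v))
}

#' Simulate observations from the dynamic coregionalization model
#'
#' Draws the latent temporal state from its stationary distribution (or a
#' supplied initial value), propagates the Markov dynamics, draws the spatial
#' components independently over days, adds the covariate mean and
#' measurement noise, and applies independent missingness per (entry, day).
#'
#' @param psi a [dcm_parameters()] (stable G required)
#' @param network a [dcm_network()]
#' @param covariates a [dcm_covariates()] with a station view, or `NULL` when
#'   `psi$beta` is `NULL`
#' @param T number of days
#' @param missing per-pollutant missingness probability (recycled to q)
#' @param seed RNG seed (reproducible draws)
#' @param z0 optional fixed initial state (length p); default stationary draw
#' @param dates optional `Date` vector of length `T`
#' @return list with `obs` (a [dcm_observations()]) and `latent`
#'   (`z` p x T, `u`, `w` N x T fields, scaled)
#' @export
simulate_dcm <- function(psi, network, covariates = NULL, T, missing = 0,
                         seed = NULL, z0 = NULL, dates = NULL) {
  validate_parameters(psi)
  cfg <- psi$config
  if (!is.null(seed)) set.seed(seed)
  pol <- entry_pollutant(network)
  N <- length(pol); p <- cfg$p
  missing <- rep_len(missing, cfg$q)
  D <- network_distances(network)
  H <- entry_loadings(cfg, pol)

  # latent temporal state
  Pinf <- stationary_covariance(psi$G, psi$Sigma_eta)
  Lz <- chol_psd(Pinf); Le <- chol_psd(psi$Sigma_eta)
  z <- matrix(0, p, T)
  zprev <- if (is.null(z0)) as.vector(Lz %*% rnorm(p)) else z0
  for (t in seq_len(T)) {
    zprev <- as.vector(psi$G %*% zprev + Le %*% rnorm(p))
    z[, t] <- zprev
  }

  # spatial components (iid over days)
  ufield <- matrix(0, N, T)
  if (cfg$include_u) {
    for (i in seq_len(cfg$q)) {
      rows <- which(pol == i)
      Lu <- chol_psd(exp(-D[rows, rows, drop = FALSE] / psi$theta[i]))
      ufield[rows, ] <- psi$alpha[i] * (Lu %*% matrix(rnorm(length(rows) * T), ncol = T))
    }
  }
  wfield <- matrix(0, N, T)
  if (cfg$include_w) {
    for (j in seq_len(cfg$n_lcm)) {
      Cw <- psi$V[[j]][cbind(rep(pol, N), rep(pol, each = N))] *
        exp(-D / psi$theta_tilde[j])
      Lw <- chol_psd(Cw)
      wfield <- wfield + Lw %*% matrix(rnorm(N * T), ncol = T)
    }
    wfield <- psi$lambda[pol] * wfield
  }

  mu <- if (is.null(psi$beta)) matrix(0, N, T) else build_mean(psi, covariates, pol)
  eps <- sqrt(psi$sigma2[pol]) * matrix(rnorm(N * T), N, T)
  Y <- mu + H %*% z + ufield + wfield + eps

  signal <- Y - eps                      # noise-free concentration field
  miss <- matrix(runif(N * T), N, T) < missing[pol]
  Y[miss] <- NA_real_
  if (is.null(dates)) dates <- seq_len(T)
  list(obs = dcm_observations(network, dates, Y),
       latent = list(z = z, u = ufield, w = wfield, signal = signal))
}

# covariance of the stacked latent state (z_1', ..., z_T')' under the
# stationary law: Cov(z_t, z_s) = G^(t-s) P_inf for t >= s
z_joint_covariance <- function(G, Sigma_eta, T) {
  p <- nrow(G)
  Pinf <- stationary_covariance(G, Sigma_eta)
  Gpow <- vector("list", T); Gpow[[1]] <- diag(p)
  if (T > 1) for (k in 2:T) Gpow[[k]] <- Gpow[[k - 1]] %*% G
  S <- matrix(0, p * T, p * T)
  for (t in seq_len(T)) for (s in seq_len(t)) {
    blk <- Gpow[[t - s + 1]] %*% Pinf
    S[((t - 1) * p + 1):(t * p), ((s - 1) * p + 1):(s * p)] <- blk
    S[((s - 1) * p + 1):(s * p), ((t - 1) * p + 1):(t * p)] <- t(blk)
  }
  sym(S)
}

# dense joint covariance of the full observation stack (all entries, all
# days, missing included) plus the loading matrix of the stacked state
dense_joint_model <- function(psi, network, T) {
  pol <- entry_pollutant(network)
  N <- length(pol); p <- psi$config$p
  H <- entry_loadings(psi$config, pol)
  Sz <- z_joint_covariance(psi$G, psi$Sigma_eta, T)
  Hbig <- matrix(0, N * T, p * T)
  for (t in seq_len(T))
    Hbig[((t - 1) * N + 1):(t * N), ((t - 1) * p + 1):(t * p)] <- H
  Ssp <- residual_covariance(psi, network, noise = TRUE)
  Sy <- Hbig %*% Sz %*% t(Hbig)
  for (t in seq_len(T)) {
    idx <- ((t - 1) * N + 1):(t * N)
    Sy[idx, idx] <- Sy[idx, idx] + Ssp
  }
  list(Sy = sym(Sy), Sz = Sz, Hbig = Hbig)
}

#' Exact log-likelihood by dense joint-Gaussian evaluation
#'
#' Marginalizes all latent components and evaluates the Gaussian log-density
#' of the observed (non-missing) data stack directly from the full joint
#' covariance. Intended for small instances (N*T up to about 2000) and as the
#' independent route against the Kalman-filter likelihood.
#'
#' @param obs a [dcm_observations()]
#' @param covariates a [dcm_covariates()] or `NULL`
#' @param psi a [dcm_parameters()]
#' @return scalar log-likelihood
#' @export
loglik_exact <- function(obs, covariates, psi) {
  validate_parameters(psi)
  net <- obs$network
  N <- n_entries(net); T <- ncol(obs$values)
  if (N * T > 4000) stop("instance too large for dense evaluation")
  pol <- entry_pollutant(net)
  mu <- if (is.null(psi$beta)) matrix(0, N, T) else build_mean(psi, covariates, pol)
  y <- as.vector(obs$values)      # stacked by day
  m <- as.vector(mu)
  keep <- !is.na(y)
  jm <- dense_joint_model(psi, net, T)
  S <- jm$Sy[keep, keep, drop = FALSE]
  r <- y[keep] - m[keep]
  L <- chol(sym(S) + diag(1e-10, nrow(S)))
  w <- backsolve(L, r, transpose = TRUE)
  -0.5 * (length(r) * log(2 * pi)) - sum(log(diag(L))) - 0.5 * sum(w^2)
}
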