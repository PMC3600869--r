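# Model configuration and the full parameter set Psi of the dynamic
# coregionalization model, with the (un)constrained reparameterizations used
# by the EM covariance step, the Fisher information and the parametric
# bootstrap.

#' Model configuration for the dynamic coregionalization model
#'
#' The model for pollutant i at site s and day t is
#'   y_i(s,t) = x_i(s,t)' beta_i + [K z(t)]_i
#'              + alpha_i u_i(s,t) + lambda_i w_i(s,t) + eps_i(s,t)
#' where z(t) is a p-dimensional latent Markov state, u_i are independent
#' unit-variance Gaussian processes with their own exponential correlation
#' (the "direct" component), w is a linear model of coregionalization of
#' `n_lcm` components sharing correlation functions across pollutants, and
#' eps is white measurement noise. Each component can be switched off.
#'
#' @param q number of pollutants
#' @param p latent temporal dimension (1 or q for the index model)
#' @param pollutants pollutant names (length q)
#' @param K known q x p loading matrix; default identity (p = q) or a column
#'   of ones (p = 1)
#' @param include_u include the direct spatial component u
#' @param include_w include the coregionalization component w
#' @param n_lcm number of coregionalization components c (>= 1 when w is in)
#' @return An object of class `dcm_config`.
#' @export
dcm_config <- function(q, p = q, pollutants = NULL, K = NULL,
                       include_u = FALSE, include_w = TRUE, n_lcm = 1L) {
  stopifnot(q >= 1, p >= 1)
  if (is.null(pollutants)) pollutants <- paste0("y", seq_len(q))
  stopifnot(length(pollutants) == q)
  if (is.null(K)) {
    K <- if (p == q) diag(q) else if (p == 1L) matrix(1, q, 1) else
      stop("provide K explicitly when p is neither 1 nor q")
  }
  K <- as.matrix(K)
  stopifnot(nrow(K) == q, ncol(K) == p)
  if (include_w) stopifnot(n_lcm >= 1)
  structure(list(q = q, p = p, pollutants = pollutants, K = K,
                 include_u = include_u, include_w = include_w,
                 n_lcm = if (include_w) as.integer(n_lcm) else 0L),
            class = "dcm_config")
}

#' Parameter set Psi of the dynamic coregionalization model
#'
#' @param beta regression coefficients, k x q matrix (covariate by pollutant),
#'   or `NULL` when the model has no covariates
#' @param G p x p stable transition matrix of the latent temporal state
#' @param Sigma_eta p x p innovation covariance (PSD)
#' @param alpha,theta scales and exponential-correlation ranges (km) of the
#'   direct component u (length q); `NULL` when u is excluded
#' @param lambda scale parameters of the coregionalization component (length q)
#' @param V list of c coregionalization correlation matrices (q x q, unit
#'   diagonal, PSD)
#' @param theta_tilde ranges (km) of the c coregionalization components
#' @param sigma2 measurement-error variances (length q)
#' @param config the [dcm_config()] the parameters belong to
#' @return An object of class `dcm_parameters`.
#' @export
dcm_parameters <- function(config, beta = NULL, G, Sigma_eta,
                           alpha = NULL, theta = NULL,
                           lambda = NULL, V = NULL, theta_tilde = NULL,
                           sigma2) {
  G <- as.matrix(G); Sigma_eta <- as.matrix(Sigma_eta)
  psi <- structure(list(beta = if (!is.null(beta)) as.matrix(beta),
                        G = G, Sigma_eta = Sigma_eta,
                        alpha = alpha, theta = theta,
                        lambda = lambda,
                        V = if (!is.null(V)) lapply(V, as.matrix),
                        theta_tilde = theta_tilde,
                        sigma2 = sigma2, config = config),
                   class = "dcm_parameters")
  validate_parameters(psi)
  psi
}

#' Validate a parameter set against its configuration
#' @param psi a `dcm_parameters`
#' @return `psi`, invisibly; errors describe the violated invariant
#' @export
validate_parameters <- function(psi) {
  cfg <- psi$config
  p <- cfg$p; q <- cfg$q
  stopifnot(all(dim(psi$G) == c(p, p)), all(dim(psi$Sigma_eta) == c(p, p)))
  if (spectral_radius(psi$G) >= 1)
    stop("transition matrix G is not stable (spectral radius >= 1)")
  if (min(eigen(sym(psi$Sigma_eta), symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("Sigma_eta is not positive semi-definite")
  if (!is.null(psi$beta)) stopifnot(ncol(psi$beta) == q)
  if (cfg$include_u) {
    stopifnot(length(psi$alpha) == q, length(psi$theta) == q,
              all(psi$alpha > 0), all(psi$theta > 0))
  } else if (!is.null(psi$alpha) || !is.null(psi$theta)) {
    stop("alpha/theta present but the direct component u is excluded")
  }
  if (cfg$include_w) {
    stopifnot(length(psi$lambda) == q, all(psi$lambda > 0),
              length(psi$V) == cfg$n_lcm,
              length(psi$theta_tilde) == cfg$n_lcm,
              all(psi$theta_tilde > 0))
    for (V in psi$V) {
      stopifnot(all(dim(V) == c(q, q)))
      if (max(abs(diag(V) - 1)) > 1e-8) stop("V must have unit diagonal")
      if (min(eigen(sym(V), symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
        stop("V is not positive semi-definite")
    }
  } else if (!is.null(psi$lambda) || !is.null(psi$V)) {
    stop("lambda/V present but the coregionalization component w is excluded")
  }
  stopifnot(length(psi$sigma2) == q, all(psi$sigma2 >= 0))
  invisible(psi)
}

spectral_radius <- function(G) max(Mod(eigen(G, only.values = TRUE)$values))

sym <- function(A) (A + t(A)) / 2

#' Stationary covariance of the latent temporal state
#'
#' Solves the discrete Lyapunov equation P = G P G' + Sigma_eta.
#'
#' @param G stable p x p transition matrix
#' @param Sigma_eta p x p innovation covariance
#' @return the stationary p x p covariance
#' @export
stationary_covariance <- function(G, Sigma_eta) {
  p <- nrow(G)
  if (spectral_radius(G) >= 1) stop("G is not stable")
  A <- diag(p * p) - kronecker(G, G)
  sym(matrix(solve(A, as.vector(Sigma_eta)), p, p))
}

# ---- correlation-matrix angle parameterization ------------------------------
# V = L L' with L lower triangular, unit-norm rows, built from angles in
# (0, pi): always a valid correlation matrix, so bootstrap draws on the
# unconstrained scale map back to valid parameters.

corr_to_angles <- function(V) {
  q <- nrow(V)
  if (q == 1) return(numeric(0))
  L <- t(chol(sym(V) + diag(1e-12, q)))
  ang <- numeric(0)
  for (i in 2:q) {
    prod_sin <- 1
    for (j in 1:(i - 1)) {
      cj <- min(1, max(-1, L[i, j] / prod_sin))
      th <- acos(cj)
      th <- min(pi - 1e-9, max(1e-9, th))
      ang <- c(ang, th)
      prod_sin <- prod_sin * sin(th)
    }
  }
  ang
}

corr_from_angles <- function(ang, q) {
  L <- diag(q)
  k <- 0
  if (q > 1) for (i in 2:q) {
    prod_sin <- 1
    for (j in 1:(i - 1)) {
      k <- k + 1
      L[i, j] <- cos(ang[k]) * prod_sin
      prod_sin <- prod_sin * sin(ang[k])
    }
    L[i, i] <- prod_sin
  }
  sym(L %*% t(L))
}

# unconstrained <-> (0, pi)
angle_to_real <- function(th) log(th / (pi - th))
real_to_angle <- function(x) pi / (1 + exp(-x))

# log-Cholesky parameterization of a PD matrix (diagonal on log scale)
spd_to_logchol <- function(S) {
  L <- t(chol(sym(S) + diag(1e-12, nrow(S))))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

logchol_to_spd <- function(x, p) {
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- x
  diag(L) <- exp(diag(L))
  sym(L %*% t(L))
}

# ---- flatten / unflatten ----------------------------------------------------
# Blocks: beta (natural), G (natural, free entries), Sigma_eta (log-Cholesky),
# phi = covariance parameters of the daily observation-noise matrix
# (log alpha, log theta, log lambda, V angles on the real line, log
# theta_tilde, log sigma2).

psi_block_names <- function(psi, blocks) {
  cfg <- psi$config
  nm <- character(0)
  if ("beta" %in% blocks && !is.null(psi$beta))
    nm <- c(nm, paste0("beta.", outer(rownames_or_idx(psi$beta),
                                      cfg$pollutants, paste, sep = ".")))
  if ("G" %in% blocks)
    nm <- c(nm, paste0("G.", seq_len(cfg$p^2)))
  if ("Sigma_eta" %in% blocks)
    nm <- c(nm, paste0("Sigma_eta.", seq_len(cfg$p * (cfg$p + 1) / 2)))
  if ("phi" %in% blocks) nm <- c(nm, phi_names(cfg))
  nm
}

rownames_or_idx <- function(m) {
  if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(nrow(m)))
}

phi_names <- function(cfg) {
  nm <- character(0)
  if (cfg$include_u)
    nm <- c(nm, paste0("alpha.", cfg$pollutants), paste0("theta.", cfg$pollutants))
  if (cfg$include_w) {
    nm <- c(nm, paste0("lambda.", cfg$pollutants))
    for (j in seq_len(cfg$n_lcm))
      nm <- c(nm, paste0("V", j, ".ang", seq_len(cfg$q * (cfg$q - 1) / 2)),
              paste0("theta_tilde.", j))
  }
  c(nm, paste0("sigma2.", cfg$pollutants))
}

phi_pack <- function(psi) {
  cfg <- psi$config
  x <- numeric(0)
  if (cfg$include_u) x <- c(x, log(psi$alpha), log(psi$theta))
  if (cfg$include_w) {
    x <- c(x, log(psi$lambda))
    for (j in seq_len(cfg$n_lcm))
      x <- c(x, angle_to_real(corr_to_angles(psi$V[[j]])), log(psi$theta_tilde[j]))
  }
  c(x, log(psi$sigma2))
}

phi_unpack <- function(x, psi) {
  cfg <- psi$config; q <- cfg$q
  k <- 0
  take <- function(n) { out <- x[(k + 1):(k + n)]; k <<- k + n; out }
  if (cfg$include_u) { psi$alpha <- exp(take(q)); psi$theta <- exp(take(q)) }
  if (cfg$include_w) {
    psi$lambda <- exp(take(q))
    na <- q * (q - 1) / 2
    for (j in seq_len(cfg$n_lcm)) {
      psi$V[[j]] <- corr_from_angles(real_to_angle(take(na)), q)
      psi$theta_tilde[j] <- exp(take(1))
    }
  }
  psi$sigma2 <- exp(take(q))
  stopifnot(k == length(x))
  psi
}

# bounds on the unconstrained phi vector for the bounded M-step search:
# ranges restricted to [1, 1e4] km, scales/variances to sane magnitudes
phi_bounds <- function(cfg) {
  lo <- numeric(0); hi <- numeric(0)
  if (cfg$include_u) {
    lo <- c(lo, rep(log(1e-4), cfg$q), rep(log(1), cfg$q))
    hi <- c(hi, rep(log(1e2), cfg$q), rep(log(1e4), cfg$q))
  }
  if (cfg$include_w) {
    lo <- c(lo, rep(log(1e-4), cfg$q))
    hi <- c(hi, rep(log(1e2), cfg$q))
    na <- cfg$q * (cfg$q - 1) / 2
    for (j in seq_len(cfg$n_lcm)) {
      lo <- c(lo, rep(-12, na), log(1))
      hi <- c(hi, rep(12, na), log(1e4))
    }
  }
  lo <- c(lo, rep(log(1e-8), cfg$q))
  hi <- c(hi, rep(log(1e2), cfg$q))
  list(lower = lo, upper = hi)
}

psi_flatten <- function(psi, blocks = c("beta", "G", "Sigma_eta", "phi")) {
  x <- numeric(0)
  if ("beta" %in% blocks && !is.null(psi$beta)) x <- c(x, as.vector(psi$beta))
  if ("G" %in% blocks) x <- c(x, as.vector(psi$G))
  if ("Sigma_eta" %in% blocks) x <- c(x, spd_to_logchol(psi$Sigma_eta))
  if ("phi" %in% blocks) x <- c(x, phi_pack(psi))
  names(x) <- psi_block_names(psi, blocks)
  x
}

psi_unflatten <- function(x, psi, blocks = c("beta", "G", "Sigma_eta", "phi")) {
  cfg <- psi$config; p <- cfg$p
  k <- 0
  take <- function(n) { out <- x[(k + 1):(k + n)]; k <<- k + n; out }
  if ("beta" %in% blocks && !is.null(psi$beta))
    psi$beta <- matrix(take(length(psi$beta)), nrow(psi$beta), ncol(psi$beta),
                       dimnames = dimnames(psi$beta))
  if ("G" %in% blocks) psi$G <- matrix(take(p * p), p, p)
  if ("Sigma_eta" %in% blocks) psi$Sigma_eta <- logchol_to_spd(take(p * (p + 1) / 2), p)
  if ("phi" %in% blocks) psi <- phi_unpack(take(length(phi_pack(psi))), psi)
  stopifnot(k == length(x))
  psi
}
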