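# Covariance construction for the spatial components of the model: the
# direct component u (per-pollutant exponential correlation), the linear
# model of coregionalization w (scaled cross-correlation matrices V_j sharing
# a correlation function per component) and white measurement error.

#' Exponential spatial correlation
#'
#' `exp(-h / theta)`: 1 at distance zero, strictly decreasing, about 0.05 at
#' three times the range.
#'
#' @param h separation distance (km), >= 0
#' @param theta correlation range (km), > 0
#' @return correlation in (0, 1]
#' @export
exp_correlation <- function(h, theta) {
  if (any(theta <= 0)) stop("theta must be > 0")
  if (any(h < 0)) stop("distances must be >= 0")
  exp(-h / theta)
}

# N x N covariance of the daily spatial residual over network entries:
# u-part (block diagonal over pollutants) + w-part + optional nugget.
# D: inter-entry distances (km); pol: per-entry pollutant index.
spatial_covariance_matrix <- function(psi, D, pol, noise = TRUE) {
  cfg <- psi$config
  N <- length(pol)
  S <- matrix(0, N, N)
  if (cfg$include_u) {
    # u_i processes are independent across pollutants and each has its own
    # range, so fill per pollutant block
    S_u <- matrix(0, N, N)
    for (i in seq_len(cfg$q)) {
      rows <- which(pol == i)
      if (length(rows))
        S_u[rows, rows] <- psi$alpha[i]^2 * exp(-D[rows, rows, drop = FALSE] / psi$theta[i])
    }
    S <- S + S_u
  }
  if (cfg$include_w) {
    lam <- psi$lambda[pol]
    LL <- lam %o% lam
    for (j in seq_len(cfg$n_lcm))
      S <- S + LL * psi$V[[j]][cbind(rep(pol, N), rep(pol, each = N))] *
        exp(-D / psi$theta_tilde[j])
  }
  if (noise) S <- S + diag(psi$sigma2[pol], N)
  sym(S)
}

# cross-covariance (no nugget) between target entries (pol0 at distances
# Dc[targets, network-entries]) and the network entries
cross_spatial_covariance <- function(psi, Dc, pol0, pol) {
  cfg <- psi$config
  n0 <- length(pol0); N <- length(pol)
  S <- matrix(0, n0, N)
  if (cfg$include_u) {
    for (i in seq_len(cfg$q)) {
      r0 <- which(pol0 == i); r1 <- which(pol == i)
      if (length(r0) && length(r1))
        S[r0, r1] <- psi$alpha[i]^2 * exp(-Dc[r0, r1, drop = FALSE] / psi$theta[i])
    }
  }
  if (cfg$include_w) {
    LL <- psi$lambda[pol0] %o% psi$lambda[pol]
    for (j in seq_len(cfg$n_lcm))
      S <- S + LL * psi$V[[j]][cbind(rep(pol0, N), rep(pol, each = n0))] *
        exp(-Dc / psi$theta_tilde[j])
  }
  S
}

# prior (marginal) variance of the spatial components, no nugget
prior_spatial_variance <- function(psi, pol0) {
  cfg <- psi$config
  v <- numeric(length(pol0))
  if (cfg$include_u) v <- v + psi$alpha[pol0]^2
  if (cfg$include_w) v <- v + cfg$n_lcm * psi$lambda[pol0]^2
  v
}

#' Residual covariance over the observed entries of one day
#'
#' Builds the symmetric PSD covariance of the daily observation residual
#' (direct component + coregionalization + measurement error) restricted to a
#' set of observed entries. The entry for (pollutant i at s; pollutant i' at
#' s') is `alpha_i alpha_i' 1{i=i'} rho(h; theta_i) + sum_j lambda_i
#' lambda_i' V_j[i,i'] rho(h; theta_tilde_j) + sigma2_i 1{i=i', s=s'}`.
#'
#' @param psi a [dcm_parameters()]
#' @param network a [dcm_network()]
#' @param subset integer/logical index of observed entries (default all)
#' @param noise include the measurement-error nugget (default `TRUE`)
#' @return covariance matrix over the selected entries
#' @export
residual_covariance <- function(psi, network, subset = NULL, noise = TRUE) {
  pol <- entry_pollutant(network)
  if (is.null(subset)) subset <- seq_along(pol)
  if (is.logical(subset)) subset <- which(subset)
  if (length(subset) < 1) stop("subset selects no entries")
  if (any(subset < 1 | subset > length(pol))) stop("unknown site in mask")
  D <- network_distances(network)[subset, subset, drop = FALSE]
  spatial_covariance_matrix(psi, D, pol[subset], noise = noise)
}

# per-entry loading rows of K (N x p); H[e, ] = K[pollutant(e), ]
entry_loadings <- function(config, pol) {
  config$K[pol, , drop = FALSE]
}

# mean matrix X beta over entries/days (N x T); zero when no covariates
build_mean <- function(psi, covariates, pol, view = c("station", "grid"),
                       rows = NULL) {
  view <- match.arg(view)
  if (is.null(psi$beta)) {
    if (is.null(covariates) || is.null(covariates[[view]]))
      stop("cannot infer T without covariates; pass mean explicitly")
    return(matrix(0, length(pol), dim(covariates[[view]])[3]))
  }
  X <- covariates[[view]]
  if (is.null(X)) stop("covariates have no ", view, " view")
  if (!is.null(rows)) X <- X[rows, , , drop = FALSE]
  Tn <- dim(X)[3]
  Bent <- t(psi$beta)[pol, , drop = FALSE]  # n x k
  out <- matrix(0, length(pol), Tn)
  for (t in seq_len(Tn)) out[, t] <- rowSums(X[, , t, drop = TRUE] * Bent)
  out
}

# design cube (N x (k q) x T) with per-pollutant coefficient blocks, used by
# the GLS beta update
build_design <- function(covariates, q, pol, view = "station", rows = NULL) {
  X <- covariates[[view]]
  if (!is.null(rows)) X <- X[rows, , , drop = FALSE]
  k <- dim(X)[2]; Tn <- dim(X)[3]; n <- length(pol)
  out <- array(0, dim = c(n, k * q, Tn))
  for (i in seq_len(q)) {
    r <- which(pol == i)
    if (length(r))
      out[r, ((i - 1) * k + 1):(i * k), ] <- X[r, , , drop = FALSE]
  }
  out
}
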