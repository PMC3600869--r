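test_that("smoother with T = 1 equals the conditional-normal update of the stationary prior", {
  mx <- make_micro_example()
  obs1 <- dcm_observations(mx$network, 1L, mx$obs$values[, 1, drop = FALSE])
  cov1 <- dcm_covariates("x1", mx$covariates$station[, , 1, drop = FALSE])
  sm <- kalman_smooth(obs1, cov1, mx$psi)
  # closed form: prior z ~ N(0, G Pinf G' + Sigma_eta) = N(0, Pinf)
  pol <- entry_pollutant(mx$network)
  H <- mx$config$K[pol, ]
  Pinf <- stationary_covariance(mx$psi$G, mx$psi$Sigma_eta)
  S <- residual_covariance(mx$psi, mx$network)
  mu <- dcmair:::build_mean(mx$psi, cov1, pol)
  Fm <- H %*% Pinf %*% t(H) + S
  r <- obs1$values[, 1] - mu[, 1]
  zhat <- Pinf %*% t(H) %*% solve(Fm, r)
  Pz <- Pinf - Pinf %*% t(H) %*% solve(Fm, H %*% Pinf)
  expect_lt(max(abs(sm$z[, 2] - zhat)), 1e-10)
  expect_lt(max(abs(sm$P[, , 2] - Pz)), 1e-10)
})

test_that("a fully missing day propagates the prior and does not gain information", {
  mx <- make_micro_example()
  Y <- mx$obs$values
  Y[, 3] <- NA
  obs <- dcm_observations(mx$network, 1:4, Y)
  sm <- kalman_smooth(obs, mx$covariates, mx$psi)
  # the empty day still matches the dense joint-Gaussian conditional
  oc <- oracle_smoother(mx$psi, obs, mx$covariates)
  expect_lt(max(abs(sm$z[, 2:5] - oc$z)), 1e-8)
  # and carries at least as much uncertainty as its observed neighbours
  expect_true(all(diag(sm$P[, , 4]) >=
                    pmin(diag(sm$P[, , 3]), diag(sm$P[, , 5])) - 1e-12))
})

test_that("EM on a temporal-only model reaches the GLS/ML fixed point", {
  set.seed(31)
  cfg <- dcm_config(1, 1, "A", include_u = FALSE, include_w = FALSE)
  psi_true <- dcm_parameters(cfg, beta = matrix(c(1.5, -0.7), 2, 1),
                             G = matrix(0.6), Sigma_eta = matrix(0.2),
                             sigma2 = 0.3)
  sites <- data.frame(pollutant = "A", station = paste0("s", 1:4),
                      lon = runif(4, 0, 100), lat = runif(4, 0, 100))
  net <- dcm_network(sites, dist_method = "planar")
  Xs <- array(rnorm(4 * 2 * 40), dim = c(4, 2, 40))
  cov <- dcm_covariates(c("x1", "x2"), Xs)
  sim <- simulate_dcm(psi_true, net, cov, T = 40, missing = 0, seed = 5)
  fit <- em_fit(sim$obs, cov, cfg, control = list(maxit = 2000, tol = 1e-11))
  expect_true(all(diff(fit$trace) > -1e-6))

  # fixed-point identity: beta equals the GLS solution given the smoothed
  # state (under the EM prior, which is held fixed across iterations)
  pol <- entry_pollutant(net)
  H <- matrix(1, 4, 1)
  S <- residual_covariance(fit$psi, net)
  Tn <- 40
  sm_em <- kalman_smooth(sim$obs, cov, fit$psi, init = "fixed", P0_scale = 10)
  Z1 <- sm_em$z[, 2:(Tn + 1), drop = FALSE]
  X <- dcmair:::build_design(cov, 1, pol)
  A <- matrix(0, 2, 2); b <- numeric(2)
  Si <- solve(S)
  for (t in 1:Tn) {
    r <- sim$obs$values[, t] - H %*% Z1[, t]
    A <- A + t(X[, , t]) %*% Si %*% X[, , t]
    b <- b + t(X[, , t]) %*% Si %*% r
  }
  expect_lt(max(abs(solve(A, b) - as.vector(fit$psi$beta))), 2e-4)

  # direct numerical maximization of the same state-space likelihood cannot
  # beat the EM optimum by a visible margin
  x0 <- dcmair:::psi_flatten(fit$psi)
  nll <- function(x) {
    ps <- dcmair:::psi_unflatten(x, fit$psi)
    if (dcmair:::spectral_radius(ps$G) >= 1) return(1e10)
    -kalman_smooth(sim$obs, cov, ps, init = "fixed", P0_scale = 10)$loglik
  }
  opt <- optim(x0, nll, method = "BFGS",
               control = list(maxit = 300, reltol = 1e-13))
  ll_em <- tail(fit$trace, 1)
  expect_lt(-opt$value - ll_em, 1e-5)
})

test_that("Fisher information recovers the closed form for a Gaussian mean", {
  # y_t = beta + eps, known variance: information n / sigma^2
  cfg <- dcm_config(1, 1, "A", include_u = FALSE, include_w = FALSE)
  psi <- dcm_parameters(cfg, beta = matrix(1.2), G = matrix(0.1),
                        Sigma_eta = matrix(1e-10), sigma2 = 0.49)
  net <- dcm_network(data.frame(pollutant = "A", station = "s1",
                                lon = 0, lat = 0), dist_method = "planar")
  n <- 60
  Xs <- array(1, dim = c(1, 1, n))
  cov <- dcm_covariates("const", Xs)
  set.seed(8)
  obs <- dcm_observations(net, 1:n, matrix(rnorm(n, 1.2, 0.7), 1, n))
  fit <- plugin_fit(psi, obs, cov)
  fi <- fisher_information(fit, blocks = "beta")
  expect_equal(as.vector(fi$information), n / 0.49, tolerance = 1e-2)
  expect_lt(max(abs(fi$information - t(fi$information))), 1e-8)
  expect_equal(unname(fi$sd), sqrt(0.49 / n), tolerance = 1e-2)
})

test_that("LOSO with a co-located duplicate and near-zero nugget reproduces the neighbour", {
  set.seed(12)
  cfg <- dcm_config(1, 1, "A", include_u = FALSE, include_w = TRUE)
  psi <- dcm_parameters(cfg, G = matrix(0.5), Sigma_eta = matrix(0.05),
                        lambda = 1, V = list(matrix(1)), theta_tilde = 50,
                        sigma2 = 1e-8)
  sites <- data.frame(pollutant = "A", station = paste0("s", 1:5),
                      lon = c(10, 10, 60, 90, 40), lat = c(20, 20, 70, 30, 90))
  net <- dcm_network(sites, dist_method = "planar")
  sim <- simulate_dcm(psi, net, NULL, T = 25, missing = 0, seed = 3)
  cv <- loso_crossval(plugin_fit(psi, sim$obs))
  # station s1 is co-located with s2: held-out residual = noise difference ~ 0
  expect_lt(max(abs(cv$residuals[1, ])), 1e-3)
  expect_true(all(cv$cmse >= cv$insample_mse))
})

test_that("single-station pollutants are flagged in cross-validation output", {
  sc <- make_scenario(q = 2, stations = c(4L, 1L), T = 25,
                      grid_dim = c(8, 8), cell_km = 15, n_covariates = 2,
                      psi = default_scenario_parameters(2, 2, c("NO2", "O3")),
                      seed = 2)
  cv <- loso_crossval(plugin_fit(sc$psi, sc$obs, sc$covariates))
  expect_identical(cv$single_station_pollutants, "O3")
})
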