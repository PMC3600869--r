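test_that("exponential correlation behaves as a correlation function", {
  expect_equal(exp_correlation(0, 37), 1)
  expect_equal(exp_correlation(50, 50), exp(-1))
  # correlation at three times the range is about 0.05
  expect_equal(round(exp_correlation(3 * 80, 80), 2), 0.05)
  expect_error(exp_correlation(10, 0), "theta")
  h <- seq(0, 200, by = 5)
  expect_true(all(diff(exp_correlation(h, 60)) < 0))
})

test_that("residual covariance entries follow the u + w + nugget formula", {
  # q = 1, one site, direct component only: variance alpha^2 + sigma^2
  cfg1 <- dcm_config(1, 1, "A", include_u = TRUE, include_w = FALSE)
  psi1 <- dcm_parameters(cfg1, G = 0.5, Sigma_eta = 0.1,
                         alpha = 0.8, theta = 50, sigma2 = 0.09)
  net1 <- dcm_network(data.frame(pollutant = "A", station = "s1",
                                 lon = 0, lat = 0), dist_method = "planar")
  expect_equal(as.vector(residual_covariance(psi1, net1)), 0.8^2 + 0.09)

  # q = 2, two co-located sites, different pollutants: cross-cov lambda1 lambda2 V12
  cfg2 <- dcm_config(2, 2, c("A", "B"), include_u = FALSE, include_w = TRUE)
  psi2 <- dcm_parameters(cfg2, G = diag(0.4, 2), Sigma_eta = diag(0.05, 2),
                         lambda = c(0.5, 0.7),
                         V = list(matrix(c(1, 0.4, 0.4, 1), 2)),
                         theta_tilde = 35, sigma2 = c(0.1, 0.2))
  net2 <- dcm_network(data.frame(pollutant = c("A", "B"),
                                 station = c("s1", "s2"),
                                 lon = c(3, 3), lat = c(7, 7)),
                      dist_method = "planar")
  S <- residual_covariance(psi2, net2)
  expect_equal(S[1, 2], 0.5 * 0.7 * 0.4)
  expect_error(residual_covariance(psi2, net2, subset = c(1, 5)), "unknown site")
})

test_that("residual covariance is symmetric PSD for random parameter sets", {
  set.seed(42)
  for (i in 1:300) {
    q <- sample(2:3, 1)
    psi <- random_psi(q, include_u = runif(1) < 0.5, include_w = TRUE)
    n <- 5L
    sites <- data.frame(pollutant = rep(paste0("P", 1:q), each = n),
                        station = paste0("s", 1:(n * q)),
                        lon = runif(n * q, 0, 150), lat = runif(n * q, 0, 150))
    net <- dcm_network(sites, paste0("P", 1:q), dist_method = "planar")
    S <- residual_covariance(psi, net)
    expect_lt(max(abs(S - t(S))), 1e-12)
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("simulation is reproducible and reduces to the mean when noiseless", {
  mx <- make_micro_example()
  a <- simulate_dcm(mx$psi, mx$network, mx$covariates, T = 4,
                    missing = 0.2, seed = 99)
  b <- simulate_dcm(mx$psi, mx$network, mx$covariates, T = 4,
                    missing = 0.2, seed = 99)
  expect_identical(a$obs$values, b$obs$values)

  # all variance parameters ~0 and z0 = 0: output equals X beta exactly
  psi0 <- mx$psi
  psi0$Sigma_eta <- diag(1e-30, 2)
  psi0$alpha <- rep(1e-15, 2); psi0$lambda <- rep(1e-15, 2)
  psi0$sigma2 <- rep(1e-30, 2)
  s0 <- simulate_dcm(psi0, mx$network, mx$covariates, T = 4, seed = 1,
                     z0 = c(0, 0))
  pol <- entry_pollutant(mx$network)
  mu <- dcmair:::build_mean(psi0, mx$covariates, pol)
  expect_lt(max(abs(s0$obs$values - mu)), 1e-10)
  expect_error(simulate_dcm(dcm_parameters(mx$config, beta = mx$psi$beta,
                                           G = diag(1.2, 2),
                                           Sigma_eta = diag(0.1, 2),
                                           alpha = c(1, 1), theta = c(10, 10),
                                           lambda = c(1, 1),
                                           V = mx$psi$V, theta_tilde = 35,
                                           sigma2 = c(0.1, 0.1)),
                            mx$network, mx$covariates, T = 3), "stable")
})

test_that("stationary state covariance solves the Lyapunov identity and matches long simulations", {
  G <- matrix(c(0.6, 0.1, -0.2, 0.5), 2, 2)
  Se <- matrix(c(0.09, 0.02, 0.02, 0.16), 2, 2)
  P <- stationary_covariance(G, Se)
  expect_lt(max(abs(P - (G %*% P %*% t(G) + Se))), 1e-12)

  # single station, long run: sample covariance of y close to the analytic one
  cfg <- dcm_config(1, 1, "A", include_u = TRUE, include_w = FALSE)
  psi <- dcm_parameters(cfg, G = 0.5, Sigma_eta = 0.12,
                        alpha = 0.6, theta = 40, sigma2 = 0.2)
  net <- dcm_network(data.frame(pollutant = "A", station = "s1",
                                lon = 0, lat = 0), dist_method = "planar")
  sim <- simulate_dcm(psi, net, NULL, T = 5000, seed = 7)
  v_analytic <- stationary_covariance(matrix(0.5), matrix(0.12))[1] + 0.6^2 + 0.2
  v_sample <- var(as.vector(sim$obs$values))
  mc_se <- v_analytic * sqrt(2 / 5000) *
    sqrt(sum(0.5^(2 * (0:100))))  # AR-correlated variance estimator inflation
  expect_lt(abs(v_sample - v_analytic), 3 * mc_se)
})

test_that("exact dense log-likelihood matches closed forms and is permutation invariant", {
  # single observation, latents off: Gaussian log-density with mean x beta
  cfg <- dcm_config(1, 1, "A", include_u = FALSE, include_w = FALSE)
  psi <- dcm_parameters(cfg, beta = matrix(2), G = 0.5,
                        Sigma_eta = matrix(1e-12), sigma2 = 0.25)
  net <- dcm_network(data.frame(pollutant = "A", station = "s1",
                                lon = 0, lat = 0), dist_method = "planar")
  xv <- array(1.5, dim = c(1, 1, 1))
  obs <- dcm_observations(net, 1L, matrix(3.1))
  ll <- loglik_exact(obs, dcm_covariates("x", xv), psi)
  expect_equal(ll, dnorm(3.1, mean = 2 * 1.5, sd = sqrt(0.25 + 1e-12), log = TRUE),
               tolerance = 1e-7)

  # reordering stations leaves the likelihood unchanged
  mx <- make_micro_example()
  ll1 <- loglik_exact(mx$obs, mx$covariates, mx$psi)
  perm <- c(3, 1, 2)
  sites <- mx$network$sites
  sites2 <- rbind(sites[perm, ], sites[perm + 3, ])
  net2 <- dcm_network(sites2, c("A", "B"), dist_method = "planar")
  vals2 <- mx$obs$values[c(perm, perm + 3), ]
  xs2 <- mx$covariates$station[c(perm, perm + 3), , , drop = FALSE]
  ll2 <- loglik_exact(dcm_observations(net2, 1:4, vals2),
                      dcm_covariates("x1", xs2), mx$psi)
  expect_lt(abs(ll1 - ll2), 1e-10)
})
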