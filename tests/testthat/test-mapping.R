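test_that("kriging at an observed station with negligible nugget reproduces the observation", {
  set.seed(21)
  cfg <- dcm_config(1, 1, "A", include_u = FALSE, include_w = TRUE)
  psi <- dcm_parameters(cfg, G = matrix(0.4), Sigma_eta = matrix(0.05),
                        lambda = 0.9, V = list(matrix(1)), theta_tilde = 60,
                        sigma2 = 1e-10)
  sites <- data.frame(pollutant = "A", station = paste0("s", 1:4),
                      lon = c(10, 60, 90, 40), lat = c(20, 70, 30, 90))
  net <- dcm_network(sites, dist_method = "planar")
  sim <- simulate_dcm(psi, net, NULL, T = 10, missing = 0, seed = 4)
  fit <- plugin_fit(psi, sim$obs)
  grid <- dcm_grid(c(10, 5000), c(20, 5000), population = c(1, 1),
                   dist_method = "planar")
  mp <- krige(fit, grid, backtransform = "none")[["A"]]
  expect_lt(max(abs(mp$yhat[1, ] - sim$obs$values[1, ])), 1e-4)
  expect_lt(max(mp$sd[1, ]), 1e-4)

  # far from every station: prediction falls back to K zhat, variance to the
  # prior spatial variance plus smoothed-state uncertainty
  Tn <- 10
  zt <- fit$smoother$z[, 2:(Tn + 1)]
  expect_lt(max(abs(mp$yhat[2, ] - zt)), 1e-3)
  prior_far <- 0.9^2 + as.vector(fit$smoother$P[1, 1, 2:(Tn + 1)])
  expect_lt(max(abs(mp$sd[2, ]^2 - prior_far)), 1e-3)
})

test_that("adding an observed station never increases the kriging variance", {
  mx <- make_micro_example()
  fit1 <- plugin_fit(mx$psi, mx$obs, mx$covariates)
  T <- 4
  xg <- array(rep(sapply(1:T, function(t) sin(t / 2) + 0.02 * 35), each = 1),
              dim = c(1, 1, T))
  cov_g <- dcm_covariates("x1", mx$covariates$station, grid = xg)
  fit1$covariates <- cov_g
  grid <- dcm_grid(15, 20, population = 1, dist_method = "planar")
  v1 <- krige(fit1, grid, pollutants = "A", backtransform = "none")[["A"]]$sd^2

  # augment the network with a 5th series for pollutant A and new data
  sites2 <- rbind(mx$network$sites,
                  data.frame(pollutant = "A", station = "s4", lon = 20, lat = 10))
  net2 <- dcm_network(sites2, c("A", "B"), dist_method = "planar")
  xs2 <- array(0, dim = c(7, 1, T))
  base <- outer(net2$sites$lon + net2$sites$lat, 1:T,
                function(s, t) sin(t / 2) + 0.02 * s)
  xs2[, 1, ] <- base
  cov2 <- dcm_covariates("x1", xs2, grid = xg)
  sim2 <- simulate_dcm(mx$psi, net2, cov2, T = T, missing = 0, seed = 11)
  fit2 <- plugin_fit(mx$psi, sim2$obs, cov2)
  v2 <- krige(fit2, grid, pollutants = "A", backtransform = "none")[["A"]]$sd^2
  expect_true(all(v2 <= v1 + 1e-8))
})

test_that("block aggregation handles constant, linear and smooth fields", {
  # 4 x 4 fine grid split into 2 x 2 blocks
  g <- expand.grid(x = 1:4, y = 1:4)
  blocks <- paste0(ceiling(g$x / 2), "-", ceiling(g$y / 2))
  const <- rep(5, 16)
  expect_true(all(block_aggregate(const, g$x, g$y, blocks, "centre") == 5))
  expect_true(all(block_aggregate(const, g$x, g$y, blocks, "mean") == 5))
  lin <- g$x + 2 * g$y
  bm <- block_aggregate(lin, g$x, g$y, blocks, "mean")
  expect_equal(unname(bm["1-1", 1]), mean(lin[g$x <= 2 & g$y <= 2]))

  # centre rule vs sub-sampled mean on a smooth field: difference bounded by
  # a few percent of the field's spread at this resolution (odd block size so
  # a cell centre sits at the block centroid, as the pixel-centre rule assumes)
  set.seed(5)
  gf <- expand.grid(x = seq(0.5, 39.5, 1), y = seq(0.5, 39.5, 1))
  f <- sin(gf$x / 12) + cos(gf$y / 15) + 0.3 * sin((gf$x + gf$y) / 20)
  blk <- paste0(ceiling(gf$x / 5), "-", ceiling(gf$y / 5))
  d <- abs(block_aggregate(f, gf$x, gf$y, blk, "centre") -
             block_aggregate(f, gf$x, gf$y, blk, "mean"))
  expect_lt(max(d), 0.05 * sd(f))
})

test_that("temporal averaging is the arithmetic mean over the requested days", {
  m <- structure(list(yhat_orig = cbind(c(2, 1), c(4, 3), c(6, 5)),
                      yhat = NULL, cells = 1:2), class = "dcm_map")
  expect_equal(temporal_average_map(m, days = 2), c(4, 3))
  expect_equal(temporal_average_map(m, days = c(1, 2)), c(3, 2))
  expect_equal(temporal_average_map(m), c(4, 3))
  expect_error(temporal_average_map(m, days = integer(0)), "empty day set")
})

test_that("back-transformation honours the lognormal-mean correction", {
  rec <- structure(list(log = TRUE, center = 3, scale = 0.5, divisor = "n-1",
                        pollutants = "A"), class = "dcm_transform")
  mx <- make_micro_example()
  fit <- plugin_fit(mx$psi, mx$obs, mx$covariates)
  xg <- array(0, dim = c(1, 1, 4))
  fit$covariates <- dcm_covariates("x1", mx$covariates$station, grid = xg)
  fit$obs$transform <- structure(list(log = c(TRUE, TRUE), center = c(3, 3),
                                      scale = c(0.5, 0.5), divisor = "n-1",
                                      pollutants = c("A", "B")),
                                 class = "dcm_transform")
  grid <- dcm_grid(15, 20, population = 1, dist_method = "planar")
  m_ln <- krige(fit, grid, pollutants = "A")[["A"]]
  m_nv <- krige(fit, grid, pollutants = "A", backtransform = "naive")[["A"]]
  expect_equal(m_ln$yhat_orig,
               exp(3 + 0.5 * m_ln$yhat + 0.25 * m_ln$sd^2 / 2))
  expect_equal(m_nv$yhat_orig, exp(3 + 0.5 * m_nv$yhat))
  expect_true(all(m_ln$yhat_orig >= m_nv$yhat_orig))
})
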