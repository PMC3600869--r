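index_toy_obs <- function(values, q = 1, pollutants = "PM10") {
  n <- nrow(values) / q
  sites <- data.frame(pollutant = rep(pollutants, each = n),
                      station = paste0("s", seq_len(n * q)),
                      lon = seq_len(n * q) * 10, lat = rep(5, n * q))
  dcm_observations(dcm_network(sites, pollutants, dist_method = "planar"),
                   seq_len(ncol(values)), values)
}

test_that("fixed loadings are the station-to-network average ratios", {
  # constant series 2 / 0.5 / 0.5: network average 1, loadings 2, 0.5, 0.5
  Y <- matrix(rep(c(2, 0.5, 0.5), 30), 3, 30)
  # noiseless constant series: the noise variance legitimately collapses to
  # its floor, which the fitter flags
  fit <- suppressWarnings(build_index_model(index_toy_obs(Y), F = c(PM10 = 1),
                                            control = list(maxit = 60)))
  expect_equal(unname(fit$loadings), c(2, 0.5, 0.5))

  # homogeneous network: all loadings 1
  set.seed(6)
  Y2 <- matrix(rep(5 + rnorm(40, 0, 0.5), each = 4), 4, 40)
  fit2 <- suppressWarnings(build_index_model(index_toy_obs(Y2), F = c(PM10 = 1),
                                             control = list(maxit = 60)))
  expect_equal(unname(fit2$loadings), rep(1, 4))

  # all-missing stations are excluded with a warning (the degenerate constant
  # series also floors the noise variance, a second expected warning)
  Y3 <- Y; Y3[2, ] <- NA
  expect_warning(
    expect_warning(build_index_model(index_toy_obs(Y3), F = c(PM10 = 1),
                                     control = list(maxit = 60)),
                   "all-missing"),
    "collapse")
})

test_that("the common trend is recovered from a station panel", {
  set.seed(77)
  n <- 15; Tn <- 365
  z <- as.vector(stats::filter(rnorm(Tn, 0, sqrt(1 - 0.9^2)), 0.9,
                               method = "recursive", init = rnorm(1)))
  k <- runif(n, 0.7, 1.3)
  level <- 5
  # signal variance ~ k^2 var(level + z); noise chosen for signal-to-noise 4
  Y <- outer(k, level + z) + matrix(rnorm(n * Tn, 0, 0.5), n, Tn)
  fit <- build_index_model(index_toy_obs(Y), F = c(PM10 = 1), p = 1,
                           control = list(maxit = 100))
  zhat <- index_I1(fit)$value
  expect_gt(cor(zhat, z), 0.95)
})

test_that("I1/I2/I3 formulas and their degenerate collapses hold", {
  z <- cbind(c(1, 2, 3), c(0.5, 0.1, 0.4))
  P <- array(0, dim = c(3, 3, 2))
  P[, , 1] <- diag(3); P[, , 2] <- diag(3) * 0.04
  i2 <- index_I2(z, P)
  expect_equal(i2$value[1], 2)
  expect_equal(i2$var[1], 3 / 9)   # (1/q^2) sum_ij p_ij
  expect_equal(i2$lower, i2$value - 1.96 * sqrt(i2$var))
  i3 <- index_I3(z, P, nsim = 5000, seed = 2)
  expect_equal(i3$value, c(3, 0.5))
  expect_identical(i3$argmax, c("y3", "y1"))
  expect_true(all(i3$lower <= i3$value & i3$value <= i3$upper))
  expect_true(all(i3$value >= i2$value))

  # q = 1: all three indices coincide in value
  z1 <- matrix(c(0.3, 0.8), 1)
  P1 <- array(0.01, dim = c(1, 1, 2))
  expect_equal(index_I1(z1, P1)$value, c(0.3, 0.8))
  expect_equal(index_I2(z1, P1)$value, index_I1(z1, P1)$value)
  expect_equal(index_I3(z1, P1, nsim = 500)$value, index_I1(z1, P1)$value)
  expect_equal(index_I1(z1, P1)$upper, c(0.3, 0.8) + 1.96 * 0.1)
  # I1 refuses multi-trend input
  expect_error(index_I1(z, P), "p = 1")
  expect_error(index_I3(z, P, nsim = 50), "at least 100")
})

test_that("interval width shrinks with the state uncertainty", {
  z <- matrix(c(0.5, 1, 0.2), 3, 1)
  P_big <- array(diag(3) * 0.25, dim = c(3, 3, 1))
  P_small <- array(diag(3) * 1e-6, dim = c(3, 3, 1))
  w_big <- with(index_I3(z, P_big, nsim = 20000, seed = 3), upper - lower)
  w_small <- with(index_I3(z, P_small, nsim = 20000, seed = 3), upper - lower)
  expect_gt(w_big, w_small)
  expect_lt(w_small, 1e-2)
})

test_that("default scaling factors encode the banding-system anchors", {
  F <- default_scaling_factors(c("NO2", "O3", "PM10"))
  expect_equal(unname(F["PM10"]), 12.8)
  expect_equal(unname(F["NO2"]), 76.4)   # 764 / 10, conversion 1
  expect_equal(unname(F["O3"]), 36.0)
  F2 <- default_scaling_factors(c("NO2", "O3"), conversion = 2)
  expect_equal(unname(F2), c(38.2, 18.0))
  F3 <- default_scaling_factors(c("PM10", "SO2"), overrides = c(SO2 = 7.5))
  expect_equal(unname(F3["SO2"]), 7.5)
  expect_error(default_scaling_factors("SO2"), "no default")
})

test_that("scaling the data rescales the trend but not the loadings", {
  set.seed(9)
  n <- 6; Tn <- 120
  z <- as.vector(stats::filter(rnorm(Tn, 0, 0.3), 0.7, method = "recursive"))
  Y <- outer(runif(n, 0.8, 1.2), 4 + z) + matrix(rnorm(n * Tn, 0, 0.3), n, Tn)
  f1 <- build_index_model(index_toy_obs(Y), F = c(PM10 = 1),
                          control = list(maxit = 200))
  f3 <- build_index_model(index_toy_obs(3 * Y), F = c(PM10 = 1),
                          control = list(maxit = 200))
  expect_equal(f1$loadings, f3$loadings, tolerance = 1e-10)
  z1 <- index_I2(f1)$value
  z3 <- index_I2(f3)$value
  expect_equal(z3 / z1, rep(3, Tn), tolerance = 0.02)
})
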