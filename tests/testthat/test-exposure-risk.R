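test_that("exposure indices are population-weighted means over blocks", {
  g <- dcm_grid(1:2, 1:2, population = c(100, 300), dist_method = "planar")
  ei <- exposure_index(c(10, 20), g)
  expect_equal(ei$region, 17.5)
  expect_equal(sum(ei$block), ei$region)

  gu <- dcm_grid(1:4, 1:4, population = rep(10, 4), dist_method = "planar")
  expect_equal(exposure_index(c(1, 2, 3, 10), gu)$region, 4)

  gz <- dcm_grid(1:3, 1:3, population = c(0, 5, 5), dist_method = "planar")
  expect_equal(exposure_index(c(1000, 2, 4), gz)$region, 3)  # zero-pop ignored
  expect_error(exposure_index(c(1, 2, 3), g), "grid mismatch")
})

test_that("the cumulative exposure distribution is a proper CDF matching the mean identity", {
  g <- dcm_grid(1:2, 1:2, population = c(50, 50), dist_method = "planar")
  ce <- cumulative_exposure(c(10, 20), g)
  expect_equal(ce$cdf(15), 0.5)
  expect_equal(ce$cdf(20), 1)
  expect_equal(ce$cdf(5), 0)

  set.seed(14)
  vals <- runif(200, 5, 60)
  gg <- dcm_grid(runif(200), runif(200), population = rpois(200, 40),
                 dist_method = "planar")
  ce2 <- cumulative_exposure(vals, gg)
  expect_lt(abs(ce2$mean - exposure_index(vals, gg)$region), 1e-9)
  grid_c <- seq(0, 70, length.out = 500)
  expect_true(all(diff(ce2$cdf(grid_c)) >= 0))
  # region-average exposure invariant under block re-indexing
  perm <- sample(200)
  gp <- dcm_grid(gg$lon[perm], gg$lat[perm], population = gg$population[perm],
                 dist_method = "planar")
  expect_equal(exposure_index(vals[perm], gp)$region,
               exposure_index(vals, gg)$region)
})

test_that("daily exceedance population counts people above threshold", {
  g <- dcm_grid(1:3, 1:3, population = c(500, 200, 300), dist_method = "planar")
  vals <- cbind(c(10, 10, 10), c(60, 60, 60), c(60, 10, 10))
  expect_equal(daily_exceedance_population(vals, g, L = 50), c(0, 1000, 500))
})

test_that("the smoothed residual CDF is monotone, symmetric and consistent", {
  r <- rep(c(-1, 1), 30)
  F <- fit_residual_cdf(r)
  expect_equal(eval_residual_cdf(F, 0), 0.5, tolerance = 1e-6)
  gx <- seq(-4, 4, length.out = 1000)
  expect_true(all(diff(eval_residual_cdf(F, gx)) >= 0))
  expect_error(fit_residual_cdf(rnorm(20)), "at least 50")

  set.seed(15)
  F2 <- fit_residual_cdf(rnorm(5000))
  xs <- seq(-3, 3, length.out = 400)
  expect_lt(max(abs(eval_residual_cdf(F2, xs) - pnorm(xs))), 0.03)
  # fast interpolation agrees with the exact kernel sum
  expect_lt(max(abs(eval_residual_cdf(F2, xs) -
                      eval_residual_cdf(F2, xs, exact = TRUE))), 1e-5)
})

fake_map <- function(yhat, sd, pollutant = "A") {
  structure(list(pollutant = pollutant, yhat = as.matrix(yhat),
                 sd = as.matrix(sd), transform = NULL),
            class = "dcm_map")
}

test_that("exceedance probabilities follow 1 - F((L - yhat)/sd)", {
  m <- fake_map(matrix(2, 1, 3), matrix(0.5, 1, 3))
  expect_equal(as.vector(exceedance_probability(m, L = 2)), rep(0.5, 3))
  # non-increasing in L
  Ls <- seq(1, 4, by = 0.25)
  pis <- vapply(Ls, function(L) exceedance_probability(m, L)[1, 1], numeric(1))
  expect_true(all(diff(pis) <= 0))
  # zero kriging sd: direct indicator
  m0 <- fake_map(matrix(c(1, 3), 1, 2), matrix(0, 1, 2))
  expect_equal(as.vector(exceedance_probability(m0, L = 2)), c(0, 1))
  # threshold mapped through the transform record
  rec <- structure(list(log = TRUE, center = 0, scale = 1, divisor = "n-1",
                        pollutants = "A"), class = "dcm_transform")
  mt <- fake_map(matrix(log(30), 1, 1), matrix(1, 1, 1))
  mt$transform <- rec
  expect_equal(exceedance_probability(mt, L = 30)[1, 1], 0.5)
})

test_that("Poisson-binomial day counts: exact convolution, closed cases, moments", {
  expect_equal(day_count_distribution(rep(1, 5))$pmf, c(0, 0, 0, 0, 0, 1))
  d <- day_count_distribution(c(0.5, 0.5), M = 0)
  expect_equal(d$p_gt_M, 0.75)   # P(N >= 1)
  expect_equal(d$pmf, c(0.25, 0.5, 0.25))

  set.seed(16)
  pi <- runif(10)
  pmf <- poisbinom_pmf(pi)
  # full enumeration over all 2^10 outcomes
  enum <- rep(0, 11)
  for (m in 0:(2^10 - 1)) {
    bits <- as.integer(intToBits(m))[1:10]
    enum[sum(bits) + 1] <- enum[sum(bits) + 1] +
      prod(ifelse(bits == 1, pi, 1 - pi))
  }
  expect_lt(max(abs(pmf - enum)), 1e-12)
  # expected day count identity and M-monotonicity
  expect_lt(abs(sum(0:10 * pmf) - sum(pi)), 1e-9)
  pM <- vapply(0:10, function(M) day_count_distribution(pi, M = M)$p_gt_M,
               numeric(1))
  expect_true(all(diff(pM) <= 1e-12))
  expect_equal(pM, 1 - cumsum(pmf)[1:11], tolerance = 1e-12)
})

test_that("aggregated risk is a convex population-weighted combination", {
  g <- dcm_grid(1:3, 1:3, population = c(10, 0, 0), dist_method = "planar")
  pi <- rbind(c(0.9, 0.1), c(0.5, 0.5), c(0.2, 0.3))
  expect_equal(aggregated_risk_series(pi, g), c(0.9, 0.1))
  gu <- dcm_grid(1:3, 1:3, population = c(5, 5, 5), dist_method = "planar")
  agg <- aggregated_risk_series(matrix(0.2, 3, 4), gu)
  expect_equal(agg, rep(0.2, 4))
  agg2 <- aggregated_risk_series(pi, gu, weights = "uniform")
  expect_true(all(agg2 >= apply(pi, 2, min) & agg2 <= apply(pi, 2, max)))
})

test_that("bootstrap bands collapse with vanishing parameter uncertainty and are seeded", {
  mx <- make_micro_example()
  fit <- plugin_fit(mx$psi, mx$obs, mx$covariates)
  stat <- function(ps) c(ps$lambda, ps$sigma2)
  x0 <- dcmair:::psi_flatten(mx$psi, c("beta", "G", "Sigma_eta", "phi"))
  tiny <- structure(list(par = x0, vcov = diag(1e-20, length(x0)),
                         blocks = c("beta", "G", "Sigma_eta", "phi")),
                    class = "dcm_fisher")
  bb <- bootstrap_bands(fit, stat, R = 20, seed = 1, fisher = tiny)
  expect_lt(max(abs(bb$lower - bb$point)), 1e-6)
  expect_lt(max(abs(bb$upper - bb$point)), 1e-6)

  wide <- structure(list(par = x0, vcov = diag(0.01, length(x0)),
                         blocks = c("beta", "G", "Sigma_eta", "phi")),
                    class = "dcm_fisher")
  b1 <- bootstrap_bands(fit, stat, R = 25, seed = 7, fisher = wide)
  b2 <- bootstrap_bands(fit, stat, R = 25, seed = 7, fisher = wide)
  expect_identical(b1$draws, b2$draws)
  expect_true(all(b1$lower <= b1$point + 1e-12 & b1$point <= b1$upper + 1e-12))
})
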