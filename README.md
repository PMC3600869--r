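# dcmair

Model-based air-quality assessment at the country level, for analysts who
must turn an **unbalanced monitoring network** — each pollutant measured at
its own, partly disjoint set of stations, with 10–20% missing daily data —
into defensible statements about air quality, population exposure and
exceedance risk, with uncertainty.

## The model

The core is a dynamic coregionalization model (DCM). For pollutant
*i* at site *s* and day *t*,

    y_i(s,t) = x_i(s,t)' beta_i + [K z(t)]_i
               + alpha_i u_i(s,t) + lambda_i w_i(s,t) + eps_i(s,t)

where `z(t)` is a latent Markov state (`z(t) = G z(t-1) + eta`,
`eta ~ N(0, Sigma_eta)`) carrying shared temporal dynamics; `u_i` are
independent unit-variance Gaussian processes with per-pollutant exponential
correlation `exp(-h/theta_i)`; `w` is a linear model of coregionalization —
components with cross-correlation matrices `V_j` and correlation ranges
shared across pollutants — through which a sparsely monitored pollutant
borrows strength from the others; and `eps` is white measurement noise.

On top of the fitted model the package computes:

* **dynamic kriging maps** `yhat_i(B,t)` with prediction standard
  deviations (exact per-day conditional normals, verified against a dense
  joint-Gaussian oracle to 1e-8);
* **global air-quality indices** `I1/I2/I3` from a reduced common-trend
  model with fixed station-average loadings, with confidence intervals;
* **population exposure** (region averages, cumulative exposure
  distributions, daily counts of people above threshold) from a population
  raster;
* **exceedance risk** `pi_i(B,t) = 1 - F((L - yhat)/sigma)` with `F` the
  kernel-smoothed CDF of Studentized leave-one-site-out residuals,
  Poisson-binomial day-count distributions against an `M`-day limit, and
  parametric-bootstrap confidence bands.

Everything is exercised end-to-end on synthetic scenarios
(`make_scenario`) that emulate a three-pollutant national campaign:
clustered population raster, stations placed preferentially in populated
areas, six covariates, realistic missingness. No external data are needed.

## Worked example

```r
library(dcmair)

sc  <- make_scenario(q = 3, stations = c(12, 4, 10), T = 120, seed = 42)
fit <- em_fit(sc$obs, sc$covariates, sc$config, control = list(maxit = 150))
fit
#> dcm_fit: 29 EM iterations, converged, loglik -3096.302

round(fit$psi$beta[1:3, ], 3)     # true values: 0.45/0.31/-0.42, ...
#>       NO2     O3  PM10
#> x1  0.394 -0.256 0.089
#> x2  0.318  0.445 0.238
#> x3 -0.477 -0.212 0.451

maps <- krige(fit, sc$grid)                      # per-pollutant dynamic maps
avg  <- temporal_average_map(maps$PM10)          # yearly-average field
exposure_index(avg, sc$grid, maps$PM10$cells)$region
#> [1] 14.03652                                   # ug/m3, population-weighted

imod <- build_index_model(invert_observations(sc$obs))
i3   <- index_I3(imod, seed = 1)                 # daily index, max pollutant
i3[which.max(i3$value), c("value", "argmax", "lower", "upper")]
#>   value argmax  lower  upper
#>    2.17     O3   1.90   2.45

loso_crossval(fit)$cmse                          # held-out prediction error
#>   NO2    O3  PM10
#> 0.511 0.537 0.533                              # transformed scale
```

The fitted coefficients sit within one or two standard errors of the
generator's truth; the PM10 region-average exposure of ~14 µg/m³ is the
population-weighted mean of the back-transformed yearly map; the worst
index day is driven by the ozone-like component with its 95% Monte-Carlo
interval; and the cross-validation mean-squared errors (on the
log-standardized scale) measure genuine out-of-sample skill — they are
several times the in-sample residuals, as they should be.

A command-line pipeline mirrors these stages:

```sh
Rscript inst/cli/dcmair.R simulate --out runs/sim --seed 1
Rscript inst/cli/dcmair.R fit      --scenario runs/sim --out runs/fit
Rscript inst/cli/dcmair.R krige    --scenario runs/sim --fit runs/fit --out runs/map
Rscript inst/cli/dcmair.R risk     --scenario runs/sim --fit runs/fit \
                                   --krige runs/map --out runs/risk
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch —
simulating the default scenario, fitting by EM, kriging, and computing the
index, exposure, cross-validation and risk summaries — and writes its JSON
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/dcm-framework.Rmd`) describes the model
and its assumptions, the EM/Kalman implementation and its numerical
choices, what the synthetic generator does and does not emulate, and the
design decisions taken on points the framework leaves open.
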