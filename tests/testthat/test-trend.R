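test_that("lagged correlation honours its lag convention", {
  x <- sin(seq(0, 10, length.out = 40))
  expect_equal(lagged_pearson(x, x, 0)$r, 1)

  y <- c(rep(NA, 3), -x)[1:40]  # y(t) = -x(t - 3)
  lc <- lagged_pearson(x, y, 3)
  expect_equal(lc$r, -1)
  expect_lt(lc$p_value, 1e-10)

  expect_error(lagged_pearson(x[1:4], x[1:4], 3), "overlapping|shorter")
  expect_error(lagged_pearson(x, x, 45), "shorter")
})

test_that("lag scan finds a planted noisy coupling at 3 trimesters", {
  cc <- sim_climate_canopy(climate_spec(n_years = 27, coupling_beta = 1,
                                        lag_trimesters = 3, noise_sd = 0.05,
                                        seed = 6))
  scan <- lag_scan(cc$climate, cc$canopy, lags = 0:8)
  expect_equal(scan$lag[which.max(abs(scan$r))], 3)
})

test_that("AR1-GLS recovers a noiseless line essentially exactly", {
  y <- 0.5 + 0.25 * (1:40)
  tr <- gls_ar1_trend(y)
  expect_equal(tr$slope, 0.25, tolerance = 1e-8)
  expect_lt(tr$p_value, 1e-12)
})

test_that("AR1-GLS agrees with the mixed-model reference implementation", {
  skip_if_not_installed("nlme")
  set.seed(4)
  y <- 0.02 * (1:60) + as.numeric(arima.sim(list(ar = 0.5), 60))
  tr <- gls_ar1_trend(y)
  ref <- nlme::gls(y ~ t, data = data.frame(y = y, t = 1:60),
                   correlation = nlme::corAR1(form = ~t), method = "REML")
  expect_equal(tr$slope, unname(coef(ref)[2]), tolerance = 0.01)
  expect_equal(tr$rho,
               unname(coef(ref$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 0.011)
  expect_equal(tr$se, sqrt(vcov(ref)[2, 2]), tolerance = 0.01)
})

test_that("estimated rho is near zero for white noise", {
  set.seed(7)
  rhos <- replicate(20, gls_ar1_trend(rnorm(80))$rho)
  expect_lt(abs(median(rhos)), 0.15)
})

test_that("trend test rejects series that are too short", {
  expect_error(gls_ar1_trend(rnorm(9)), "at least 10")
})

test_that("RMA slope follows the closed form and inverts under axis swap", {
  y2 <- 2 * (1:10)
  f <- rma_fit(1:10, y2)
  expect_equal(f$slope, 2)
  expect_equal(f$r_squared, 1)

  set.seed(9)
  x <- rnorm(50); y <- 1.5 * x + rnorm(50, sd = 0.5)
  fxy <- rma_fit(x, y); fyx <- rma_fit(y, x)
  expect_equal(fxy$slope * fyx$slope, 1, tolerance = 1e-12)
  expect_equal(fxy$slope, sign(cor(x, y)) * sd(y) / sd(x))
  expect_equal(fxy$intercept, mean(y) - fxy$slope * mean(x))

  expect_error(rma_fit(rep(1, 5), 1:5), "variance")
  expect_error(rma_fit(1:2, 1:2), "at least 3")
})

test_that("spline smoother reproduces lines and saturating declines", {
  f <- smooth_fit(1:10, 2 * (1:10) + 3, df = 4)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)
  expect_equal(f$data$fitted, 2 * (1:10) + 3, tolerance = 1e-8)

  # nitrate-like decline: depleted above 8 degrees C
  tt <- seq(4, 12, length.out = 40)
  nit <- pmax(0, 8 - tt)
  f2 <- smooth_fit(tt, nit, df = 4)
  dep <- depletion_threshold(f2, above = 8, frac = 0.1)
  expect_true(dep$depleted)

  expect_error(smooth_fit(rep(1, 10), 1:10), "degenerate")
  expect_error(smooth_fit(1:5, 1:5), "at least 8")
})

test_that("the smoother interpolates in its df -> n limit", {
  set.seed(1)
  x <- sort(runif(20, 0, 10)); y <- sin(x)
  f <- smooth_fit(x, y, df = length(x) - 1)
  expect_lt(max(abs(f$data$fitted - y)), 1e-6)
})
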