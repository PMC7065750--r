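#' Lagged Pearson correlation between two trimester series
#'
#' Correlates `y(t)` with `x(t - lag)`: `x` leads `y`, so with a canopy
#' response and an ENSO-like driver the driver is passed as `x` and
#' `lag_trimesters = 3` implements the one-year lag. The two-sided p-value
#' comes from the t distribution on the overlapping length; when the inputs
#' have been smoothed (running means) the p-value is descriptive only, since
#' smoothing inflates autocorrelation.
#'
#' @param x Leading series (trimester tibble or numeric, on the same grid as `y`).
#' @param y Responding series.
#' @param lag_trimesters Lag in steps (default 3 = one year).
#' @return A `kelp_lagcor` list: `lag`, `r`, `p_value`, `n`.
#' @export
lagged_pearson <- function(x, y, lag_trimesters = 3) {
  lag <- check_count(lag_trimesters, "lag_trimesters", min = 0L)
  xv <- ts_values(x, "x")
  yv <- ts_values(y, "y")
  n <- min(length(xv), length(yv))
  if (lag >= n) abort("Lag is not shorter than the series.")
  xs <- xv[seq_len(n - lag)]
  ys <- yv[seq_len(n - lag) + lag]
  ok <- !is.na(xs) & !is.na(ys)
  if (sum(ok) < 3L) abort("Fewer than 3 overlapping observations after lagging.")
  ct <- suppressWarnings(cor.test(xs[ok], ys[ok], method = "pearson"))
  structure(
    list(lag = lag, r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok)),
    class = "kelp_lagcor"
  )
}

#' Scan lagged correlations over a range of lags
#'
#' @inheritParams lagged_pearson
#' @param lags Integer lags to evaluate (default 0:8).
#' @return A tibble with `lag`, `r`, `p_value`, `n`.
#' @export
lag_scan <- function(x, y, lags = 0:8) {
  purrr::map_dfr(lags, function(l) {
    lc <- lagged_pearson(x, y, l)
    tibble::tibble(lag = lc$lag, r = lc$r, p_value = lc$p_value, n = lc$n)
  })
}

#' @export
print.kelp_lagcor <- function(x, ...) {
  cat(sprintf("Lagged Pearson correlation: lag %d trimesters, r = %.3f, p = %.4g (n = %d)\n",
              x$lag, x$r, x$p_value, x$n))
  invisible(x)
}

#' Generalized least squares trend test with AR1 errors
#'
#' Fits `value = a + b * t` by GLS under a first-order autoregressive error
#' correlation (`cor(e_i, e_j) = rho^|t_i - t_j|`, so gaps in the series are
#' handled by the appropriate power). The AR1 coefficient is estimated by
#' profiling the restricted (REML) likelihood over a grid of rho values
#' (-0.95 to 0.95, step 0.01); the slope's standard error is computed under
#' the estimated AR1 covariance and the two-sided p-value uses a t
#' distribution on n - 2 degrees of freedom.
#'
#' @param ts Trimester-series tibble (columns `trimester`, `value`) or a
#'   numeric vector on unit steps.
#' @param rho_grid Grid of candidate AR1 coefficients.
#' @return A `kelp_trend` list: `slope`, `se`, `rho`, `p_value`, `intercept`,
#'   `n`, `df`.
#' @examples
#' y <- 0.01 * (1:40) + arima.sim(list(ar = 0.5), 40)
#' gls_ar1_trend(as.numeric(y))
#' @export
gls_ar1_trend <- function(ts, rho_grid = seq(-0.95, 0.95, by = 0.01)) {
  if (is.data.frame(ts)) {
    v <- ts_values(ts, "ts")
    t_idx <- if ("trimester" %in% names(ts)) as.numeric(ts$trimester) else seq_along(v)
  } else {
    v <- as.numeric(ts)
    t_idx <- seq_along(v)
  }
  ok <- !is.na(v)
  y <- v[ok]
  tt <- t_idx[ok]
  n <- length(y)
  if (n < 10L) abort("Need at least 10 non-missing steps for the trend test.")

  X <- cbind(1, tt)
  gaps <- diff(tt)

  fit_one <- function(rho) {
    a <- rho^gaps                      # lag-specific correlation
    s <- sqrt(1 - a^2)
    wy <- c(y[1], (y[-1] - a * y[-n]) / s)
    wX <- rbind(X[1, ], (X[-1, , drop = FALSE] - a * X[-n, , drop = FALSE]) / s)
    xtx <- crossprod(wX)
    beta <- solve(xtx, crossprod(wX, wy))
    rss <- sum((wy - wX %*% beta)^2)
    # restricted log-likelihood (constants dropped)
    reml <- -(n - 2) / 2 * log(rss) - 0.5 * sum(log(1 - a^2)) -
      0.5 * determinant(xtx, logarithm = TRUE)$modulus
    list(reml = as.numeric(reml), beta = beta, rss = rss, xtx = xtx)
  }

  fits <- lapply(rho_grid, fit_one)
  best <- which.max(vapply(fits, `[[`, numeric(1), "reml"))
  f <- fits[[best]]
  sigma2 <- f$rss / (n - 2)
  vcov <- sigma2 * solve(f$xtx)
  slope <- f$beta[2]
  se <- sqrt(vcov[2, 2])
  tval <- slope / se
  p <- 2 * pt(-abs(tval), df = n - 2)

  structure(
    list(slope = unname(slope), se = unname(se), rho = rho_grid[best],
         p_value = p, intercept = unname(f$beta[1]), n = n, df = n - 2L,
         t = unname(tval)),
    class = "kelp_trend"
  )
}

#' @export
print.kelp_trend <- function(x, ...) {
  cat(sprintf("AR1-GLS trend: slope = %.4g (se %.4g), rho = %.2f, t = %.3f, p = %.4g (n = %d)\n",
              x$slope, x$se, x$rho, x$t, x$p_value, x$n))
  invisible(x)
}

#' Reduced major axis regression
#'
#' Symmetric line fitting used when both variables carry error (e.g.
#' satellite canopy fraction against in-situ diver density):
#' `slope = sign(r) * sd(y) / sd(x)`,
#' `intercept = mean(y) - slope * mean(x)`, with `r^2` from the Pearson
#' correlation.
#'
#' @param x,y Paired numeric vectors (n >= 3, both with positive variance).
#' @return A `kelp_rma` list: `slope`, `intercept`, `r`, `r_squared`, `n`.
#' @examples
#' rma_fit(1:10, 2 * (1:10) + rnorm(10, sd = 0.1))
#' @export
rma_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) abort("Need at least 3 complete pairs.")
  if (var(x) == 0 || var(y) == 0) abort("Both variables must have positive variance.")
  r <- cor(x, y)
  slope <- sign(r) * sd(y) / sd(x)
  if (r == 0) slope <- sd(y) / sd(x)  # sign convention for exactly-zero r
  structure(
    list(slope = slope, intercept = mean(y) - slope * mean(x),
         r = r, r_squared = r^2, n = n),
    class = "kelp_rma"
  )
}

#' @export
print.kelp_rma <- function(x, ...) {
  cat(sprintf("RMA regression: slope = %.4g, intercept = %.4g, r^2 = %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Penalized cubic-spline fit of nitrate on temperature
#'
#' A univariate penalized cubic-spline smoother (default 4 effective degrees
#' of freedom) for smooth, saturating relationships such as seawater nitrate
#' concentration against temperature. Supports evaluating a depletion
#' threshold: whether fitted values above a given temperature fall near zero.
#'
#' @param x Predictor (e.g. temperature, degrees C), n >= 8, not all equal.
#' @param y Response (e.g. nitrate, uM).
#' @param df Effective degrees of freedom of the smoother (default 4).
#' @return A `kelp_smooth` list: `spline` (the fitted smoother), `data`
#'   (tibble `x`, `y`, `fitted`), `r_squared`, `df`.
#' @export
smooth_fit <- function(x, y, df = 4) {
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  if (length(x) < 8L) abort("Need at least 8 complete pairs.")
  if (var(x) == 0) abort("`x` is degenerate (all values equal).")
  df <- check_number(df, "df", min = 2)
  nx <- length(unique(x))
  df <- min(df, nx)
  fit <- if (df >= nx - 1) {
    # interpolation limit: df within 1 of the unique-x count requests a
    # (numerically) unpenalized spline through the data
    smooth.spline(x, y, lambda = 1e-12, all.knots = TRUE)
  } else {
    smooth.spline(x, y, df = df, all.knots = TRUE, cv = FALSE)
  }
  fitted <- predict(fit, x)$y
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  structure(
    list(spline = fit, data = tibble::tibble(x = x, y = y, fitted = fitted),
         r_squared = r2, df = df),
    class = "kelp_smooth"
  )
}

#' Predict from a fitted nitrate-temperature smoother
#'
#' @param object A `kelp_smooth` fit.
#' @param newdata Numeric vector of predictor values (defaults to the
#'   training values).
#' @param ... Unused.
#' @return Tibble with `x` and `fitted`.
#' @export
predict.kelp_smooth <- function(object, newdata = NULL, ...) {
  newdata <- newdata %||% object$data$x
  tibble::tibble(x = as.numeric(newdata),
                 fitted = predict(object$spline, as.numeric(newdata))$y)
}

#' Check nutrient depletion above a temperature threshold
#'
#' @param object A `kelp_smooth` fit.
#' @param above Temperature above which depletion is evaluated.
#' @param frac Depletion criterion: all fitted values above `above` must be
#'   below `frac` of the fitted maximum.
#' @return A list with `depleted` (logical), `max_fitted_above`,
#'   `fitted_max`.
#' @export
depletion_threshold <- function(object, above = 8, frac = 0.1) {
  if (!inherits(object, "kelp_smooth")) abort("`object` must be a kelp_smooth fit.")
  grid <- seq(min(object$data$x), max(object$data$x), length.out = 200)
  fitted <- predict(object, grid)$fitted
  fmax <- max(fitted)
  hi <- fitted[grid > above]
  list(
    depleted = length(hi) > 0 && all(hi < frac * fmax),
    max_fitted_above = if (length(hi)) max(hi) else NA_real_,
    fitted_max = fmax
  )
}
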