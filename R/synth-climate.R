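#' Specify a lag-coupled climate / canopy series pair
#'
#' Describes the structure used to emulate ENSO-forced kelp canopy dynamics:
#' a persistent (AR1) climate index on trimester steps and a canopy series
#' built from a seasonal cycle minus a lagged multiple of the climate index,
#' so warm (positive-index) conditions depress canopy after `lag_trimesters`
#' steps.
#'
#' @param n_years Series length in years (3 trimesters per year).
#' @param coupling_beta Effect of the lagged climate index on canopy
#'   (dimensionless; positive values mean a negative canopy response).
#' @param lag_trimesters Coupling lag in trimesters (3 = one year).
#' @param seasonal_amplitude Amplitude of the annual canopy cycle (>= 0).
#' @param noise_sd Canopy noise standard deviation.
#' @param ar1 Persistence of the climate index, in (-1, 1); ENSO-like indices
#'   are strongly persistent (default 0.8).
#' @param seed Integer seed.
#' @return A `climate_spec` list.
#' @export
climate_spec <- function(n_years = 27, coupling_beta = 1, lag_trimesters = 3,
                         seasonal_amplitude = 0.5, noise_sd = 0.05,
                         ar1 = 0.8, seed = 1) {
  n_years <- check_count(n_years, "n_years")
  lag_trimesters <- check_count(lag_trimesters, "lag_trimesters", min = 0L)
  coupling_beta <- check_number(coupling_beta, "coupling_beta")
  seasonal_amplitude <- check_number(seasonal_amplitude, "seasonal_amplitude", min = 0)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  ar1 <- check_number(ar1, "ar1", min = -0.999, max = 0.999)
  seed <- check_count(seed, "seed", min = 0L)
  if (lag_trimesters >= 3L * n_years) {
    abort("`lag_trimesters` must be shorter than the series.")
  }
  structure(
    list(n_years = n_years, coupling_beta = coupling_beta,
         lag_trimesters = lag_trimesters,
         seasonal_amplitude = seasonal_amplitude,
         noise_sd = noise_sd, ar1 = ar1, seed = seed),
    class = "climate_spec"
  )
}

#' Generate a coupled climate index and canopy trimester series
#'
#' The climate index is a standardized AR1 process; the canopy series is
#' `seasonal(t) - coupling_beta * climate(t - lag) + noise`, min-max rescaled
#' to \[0, 1\] (the scale of proportional canopy density). The climate series
#' is generated with a burn-in of `lag_trimesters` extra steps so the lagged
#' term is defined at every reported step.
#'
#' @param spec A [climate_spec()].
#' @param start_year Calendar year of the first trimester (default 1998).
#' @return A list with `climate` and `canopy`, each a trimester-series tibble
#'   (columns `trimester`, `date`, `value`, `n_obs`).
#' @examples
#' cc <- sim_climate_canopy(climate_spec(n_years = 10, seed = 4))
#' head(cc$canopy)
#' @export
sim_climate_canopy <- function(spec, start_year = 1998) {
  if (!inherits(spec, "climate_spec")) abort("`spec` must be a climate_spec().")
  n <- 3L * spec$n_years
  lag <- spec$lag_trimesters

  with_seed(spec$seed, {
    # AR1 climate with burn-in for the lagged term
    ntot <- n + lag + 50L
    e <- rnorm(ntot)
    x <- numeric(ntot)
    x[1] <- e[1] / sqrt(1 - spec$ar1^2)
    for (t in 2:ntot) x[t] <- spec$ar1 * x[t - 1] + e[t]
    x <- as.numeric(scale(x))
    climate <- x[(50L + lag + 1L):(50L + lag + n)]
    climate_lagged <- x[(50L + 1L):(50L + n)]

    season <- spec$seasonal_amplitude * cos(2 * pi * (seq_len(n) - 1) / 3)
    canopy <- season - spec$coupling_beta * climate_lagged +
      rnorm(n, sd = spec$noise_sd)
    rng <- range(canopy)
    if (rng[2] > rng[1]) canopy <- (canopy - rng[1]) / (rng[2] - rng[1])

    list(
      climate = new_trimester_series(seq_len(n), climate, rep(1L, n), start_year),
      canopy = new_trimester_series(seq_len(n), canopy, rep(1L, n), start_year)
    )
  })
}
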