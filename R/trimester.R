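#' Trimester series construction and transforms
#'
#' Canopy and climate series are carried on a regular grid of 4-month
#' trimesters, three per calendar year with boundaries fixed at
#' January-April, May-August, September-December.
#'
#' @name trimester
NULL

trimester_of_month <- function(month) (month - 1L) %/% 4L + 1L

trimester_start_date <- function(index, start_year) {
  year <- start_year + (index - 1L) %/% 3L
  month <- 1L + 4L * ((index - 1L) %% 3L)
  as.Date(sprintf("%d-%02d-01", year, month))
}

new_trimester_series <- function(trimester, value, n_obs, start_year) {
  out <- tibble::tibble(
    trimester = as.integer(trimester),
    date = trimester_start_date(as.integer(trimester), start_year),
    value = as.numeric(value),
    n_obs = as.integer(n_obs)
  )
  attr(out, "start_year") <- start_year
  class(out) <- c("trimester_series", class(out))
  out
}

ts_values <- function(x, name = "series") {
  if (is.data.frame(x)) {
    if (!"value" %in% names(x)) abort(sprintf("`%s` needs a `value` column.", name))
    as.numeric(x$value)
  } else if (is.numeric(x)) {
    as.numeric(x)
  } else {
    abort(sprintf("`%s` must be a trimester-series tibble or numeric vector.", name))
  }
}

#' Aggregate dated observations onto trimesters
#'
#' Averages all observations falling in the same calendar trimester
#' (Jan-Apr, May-Aug, Sep-Dec), then fills interior empty trimesters by
#' linear interpolation between the neighbouring observed trimesters.
#' Leading and trailing gaps are left missing (no extrapolation);
#' interpolated steps are flagged with `n_obs = 0`.
#'
#' @param series A tibble with columns `date` and `value` (e.g. from
#'   [extract_site_series()]).
#' @return A trimester-series tibble: `trimester`, `date` (trimester start),
#'   `value`, `n_obs`.
#' @examples
#' obs <- tibble::tibble(date = as.Date(c("1998-02-01", "1998-03-15", "1998-10-01")),
#'                       value = c(2, 4, 6))
#' to_trimesters(obs)
#' @export
to_trimesters <- function(series) {
  if (!is.data.frame(series) || !all(c("date", "value") %in% names(series))) {
    abort("`series` must be a tibble with `date` and `value` columns.")
  }
  obs <- dplyr::filter(series, !is.na(.data$date), !is.na(.data$value))
  if (nrow(obs) < 2L) abort("Need at least two dated observations.")

  dates <- as.Date(obs$date)
  year <- as.integer(format(dates, "%Y"))
  tri <- trimester_of_month(as.integer(format(dates, "%m")))
  start_year <- min(year)
  index <- 3L * (year - start_year) + tri

  agg <- tibble::tibble(index = index, value = obs$value) |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(value = mean(.data$value), n_obs = dplyr::n(),
                     .groups = "drop")

  full <- seq(min(agg$index), max(agg$index))
  value <- rep(NA_real_, length(full))
  n_obs <- rep(0L, length(full))
  pos <- match(agg$index, full)
  value[pos] <- agg$value
  n_obs[pos] <- as.integer(agg$n_obs)

  # interior gaps: linear interpolation between observed trimesters
  if (anyNA(value)) {
    filled <- approx(full[!is.na(value)], value[!is.na(value)],
                     xout = full, method = "linear", rule = 1)$y
    value <- filled
  }

  out <- tibble::tibble(
    trimester = full - full[1] + 1L,
    date = trimester_start_date(full, start_year),
    value = value,
    n_obs = n_obs
  )
  attr(out, "start_year") <- start_year
  class(out) <- c("trimester_series", class(out))
  out
}

#' Proportionally standardize a canopy series
#'
#' Divides all values by the series maximum, yielding proportional canopy
#' density in \[0, 1\]: this removes between-site differences in available
#' kelp habitat and focuses on relative dynamics. An all-zero series is
#' returned unchanged (documented convention: no division by zero).
#'
#' @param ts A trimester-series tibble (or any tibble with a `value` column).
#' @return The input with `value` rescaled.
#' @export
proportional_standardize <- function(ts) {
  v <- ts_values(ts, "ts")
  m <- suppressWarnings(max(v, na.rm = TRUE))
  if (is.finite(m) && m > 0) {
    if (is.data.frame(ts)) ts$value <- v / m else ts <- v / m
  }
  ts
}

#' Build the regional canopy series from fraction maps
#'
#' Sums canopy fraction over all valid pixels of each image, averages the
#' image-level sums within trimesters (absorbing tide- and current-driven
#' variation between acquisitions), and proportionally standardizes the
#' result.
#'
#' @param maps List of `fraction_map` objects with dates.
#' @param standardize Divide by the series maximum (default TRUE).
#' @return A trimester-series tibble.
#' @export
regional_series <- function(maps, standardize = TRUE) {
  obs <- purrr::map_dfr(maps, function(m) {
    tibble::tibble(
      date = if (is.null(m$date)) as.Date(NA) else as.Date(m$date),
      value = sum(m$fraction[m$valid], na.rm = TRUE)
    )
  })
  out <- to_trimesters(obs)
  if (standardize) out <- proportional_standardize(out)
  out
}

#' Centered running mean over trimesters
#'
#' A centered moving average with windows shrinking symmetrically at the
#' series edges; missing steps are excluded from each window's mean. The
#' default 6-trimester window is the 2-year smoother used to expose
#' interannual canopy and climate variation.
#'
#' @param ts A trimester-series tibble or numeric vector.
#' @param window Window length in trimesters (default 6; 1 = identity).
#' @return Input with `value` replaced by the running mean.
#' @export
running_mean <- function(ts, window = 6) {
  window <- check_count(window, "window", min = 1L)
  v <- ts_values(ts, "ts")
  n <- length(v)
  lo <- (window - 1L) %/% 2L
  hi <- window - 1L - lo
  sm <- vapply(seq_len(n), function(i) {
    w <- v[max(1L, i - lo):min(n, i + hi)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
  if (is.data.frame(ts)) {
    ts$value <- sm
    ts
  } else {
    sm
  }
}
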