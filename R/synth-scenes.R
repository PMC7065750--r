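#' Specify a synthetic multiband scene series
#'
#' Describes a stack of Landsat-like multispectral acquisitions over a kelp
#' bed: a regular pixel grid (default 30 m pixels, 6 reflective bands), a
#' Gaussian kelp patch whose per-date amplitude sets the true canopy
#' fraction, per-date seawater spectral variability, additive sensor noise,
#' and independent per-pixel cloud occlusion.
#'
#' The true canopy-fraction field defaults to
#' `amplitude[d] * exp(-dist^2 / (2 * patch_sd_m^2))`, clipped to \[0, 1\];
#' pass `truth` to supply any fraction field directly.
#'
#' @param n_rows,n_cols Pixel grid size.
#' @param pixel_size Pixel edge length in metres (default 30).
#' @param n_bands Number of reflective bands (default 6), at least 2.
#' @param dates Acquisition dates (`Date`, strictly increasing). See
#'   [sim_acquisition_dates()] for a winter-free sampling helper.
#' @param amplitude Per-date peak canopy fraction in \[0, 1\]; scalar values
#'   are recycled. Defaults to a seasonal cycle peaking in austral summer.
#' @param patch_center Patch centre `c(x, y)` in metres (default scene centre).
#' @param patch_sd_m Gaussian radius of the patch in metres (default one sixth
#'   of the scene width).
#' @param truth Optional `n_rows x n_cols x length(dates)` array of true
#'   fractions in \[0, 1\], overriding the Gaussian patch.
#' @param water_variability Per-date standard deviation (reflectance units) of
#'   the perturbation applied to each seawater endmember.
#' @param noise_sd Additive per-band Gaussian noise (reflectance units).
#' @param cloud_prob Per-pixel, per-date probability of cloud occlusion.
#' @param seed Integer seed.
#'
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_rows = 16, n_cols = 16, pixel_size = 30, n_bands = 6,
                       dates = sim_acquisition_dates(1998, 4, per_year = 6, seed = seed),
                       amplitude = NULL, patch_center = NULL, patch_sd_m = NULL,
                       truth = NULL, water_variability = 0.002,
                       noise_sd = 0.002, cloud_prob = 0.05, seed = 1) {
  seed <- check_count(seed, "seed", min = 0L)
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  n_bands <- check_count(n_bands, "n_bands", min = 2L)
  pixel_size <- check_number(pixel_size, "pixel_size", min = 1e-6)
  water_variability <- check_number(water_variability, "water_variability", min = 0)
  noise_sd <- check_number(noise_sd, "noise_sd", min = 0)
  cloud_prob <- check_number(cloud_prob, "cloud_prob", min = 0, max = 1)

  dates <- as.Date(dates)
  if (length(dates) < 1L || anyNA(dates)) abort("`dates` must be valid dates.")
  if (any(diff(dates) <= 0)) abort("`dates` must be strictly increasing.")
  nd <- length(dates)

  if (is.null(amplitude)) {
    doy <- as.integer(format(dates, "%j"))
    # austral-summer peak (~mid February)
    amplitude <- 0.5 + 0.45 * cos(2 * pi * (doy - 45) / 365.25)
  }
  amplitude <- rep_len(as.numeric(amplitude), nd)
  if (anyNA(amplitude) || any(amplitude < 0 | amplitude > 1)) {
    abort("`amplitude` values must lie in [0, 1].")
  }

  if (is.null(patch_center)) {
    patch_center <- c(n_cols * pixel_size / 2, n_rows * pixel_size / 2)
  }
  if (is.null(patch_sd_m)) patch_sd_m <- n_cols * pixel_size / 6

  if (!is.null(truth)) {
    truth <- as.array(truth)
    if (!all(dim(truth) == c(n_rows, n_cols, nd))) {
      abort("`truth` must be an n_rows x n_cols x n_dates array.")
    }
    if (anyNA(truth) || any(truth < 0 | truth > 1)) {
      abort("`truth` fractions must lie in [0, 1].")
    }
  }

  structure(
    list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size,
         n_bands = n_bands, dates = dates, amplitude = amplitude,
         patch_center = as.numeric(patch_center),
         patch_sd_m = as.numeric(patch_sd_m), truth = truth,
         water_variability = water_variability, noise_sd = noise_sd,
         cloud_prob = cloud_prob, seed = seed),
    class = "scene_spec"
  )
}

#' Sample acquisition dates outside the austral winter
#'
#' High-latitude southern-hemisphere optical imagery is only usable between
#' August and April (winter sun angles are too low), so acquisition dates are
#' drawn from August through April of each season.
#'
#' @param start_year First acquisition season (the season spans August of
#'   `start_year` to April of `start_year + 1`).
#' @param n_years Number of seasons.
#' @param per_year Acquisitions per season (months sampled without
#'   replacement from August to April).
#' @param seed Integer seed.
#' @return Strictly increasing `Date` vector.
#' @export
sim_acquisition_dates <- function(start_year, n_years, per_year = 6, seed = 1) {
  start_year <- check_count(start_year, "start_year", min = 1900L)
  n_years <- check_count(n_years, "n_years")
  per_year <- check_count(per_year, "per_year")
  if (per_year > 9L) abort("`per_year` cannot exceed the 9 usable months.")
  seed <- check_count(seed, "seed", min = 0L)
  with_seed(seed + 101L, {
    dates <- lapply(seq_len(n_years) - 1L, function(k) {
      months <- sort(sample(c(8:12, 1:4), per_year))
      yr <- ifelse(months <= 4L, start_year + k + 1L, start_year + k)
      as.Date(sprintf("%d-%02d-%02d", yr, months, sample(1:28, per_year, replace = TRUE)))
    })
    sort(unique(do.call(c, dates)))
  })
}

#' Generate a synthetic scene stack with known canopy truth
#'
#' Renders each acquisition of a [scene_spec()]: every unmasked pixel is the
#' linear mixture `f * kelp + (1 - f) * w + noise` where `f` is the pixel's
#' true canopy fraction and `w` a randomly drawn (date-perturbed) seawater
#' endmember. The true fraction field and cloud masks are returned alongside
#' the reflectance cubes, so downstream unmixing has a recovery target.
#'
#' @param spec A [scene_spec()].
#' @param library An [sim_endmember_library()] result with matching band count.
#' @return A `scene_stack`: list with `scenes` (list of
#'   `n_rows x n_cols x n_bands` arrays), `cloud` (list of logical matrices,
#'   `TRUE` = obscured), `truth` (list of fraction matrices), `dates`, grid
#'   metadata and the spec.
#' @examples
#' lib <- sim_endmember_library(5, 6, seed = 2)
#' stack <- sim_scene_series(scene_spec(n_rows = 8, n_cols = 8, seed = 2), lib)
#' length(stack$scenes)
#' @export
sim_scene_series <- function(spec, library) {
  if (!inherits(spec, "scene_spec")) abort("`spec` must be a scene_spec().")
  validate_library(library, n_bands = spec$n_bands)

  nr <- spec$n_rows; nc <- spec$n_cols; nb <- spec$n_bands
  nd <- length(spec$dates)
  npix <- nr * nc
  K <- nrow(library$water)

  # pixel-centre coordinates (x east, y north, row 1 = top)
  cx <- (rep(seq_len(nc), each = nr) - 0.5) * spec$pixel_size
  cy <- ((nr - rep(seq_len(nr), times = nc)) + 0.5) * spec$pixel_size
  d2 <- (cx - spec$patch_center[1])^2 + (cy - spec$patch_center[2])^2
  shape <- exp(-d2 / (2 * spec$patch_sd_m^2))

  with_seed(spec$seed, {
    out_scenes <- vector("list", nd)
    out_cloud <- vector("list", nd)
    out_truth <- vector("list", nd)
    for (d in seq_len(nd)) {
      f <- if (is.null(spec$truth)) {
        pmin(1, pmax(0, spec$amplitude[d] * shape))
      } else {
        as.numeric(spec$truth[, , d])
      }
      wlib <- library$water +
        matrix(rnorm(K * nb, sd = spec$water_variability), K, nb)
      widx <- sample.int(K, npix, replace = TRUE)
      refl <- f %o% library$kelp + (1 - f) * wlib[widx, , drop = FALSE] +
        matrix(rnorm(npix * nb, sd = spec$noise_sd), npix, nb)
      cloud <- matrix(runif(npix) < spec$cloud_prob, nr, nc)
      out_scenes[[d]] <- array(refl, dim = c(nr, nc, nb))
      out_cloud[[d]] <- cloud
      out_truth[[d]] <- matrix(f, nr, nc)
    }
    structure(
      list(scenes = out_scenes, cloud = out_cloud, truth = out_truth,
           dates = spec$dates, n_rows = nr, n_cols = nc, n_bands = nb,
           pixel_size = spec$pixel_size, seed = spec$seed),
      class = "scene_stack"
    )
  })
}

#' @export
print.scene_stack <- function(x, ...) {
  cat(sprintf("<scene_stack> %d dates, %dx%d pixels (%g m), %d bands\n",
              length(x$dates), x$n_rows, x$n_cols, x$pixel_size, x$n_bands))
  invisible(x)
}
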