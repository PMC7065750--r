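#' Unmix one pixel against a kelp/seawater endmember pair
#'
#' Solves the two-endmember sum-to-one linear mixing model
#' `r = f * kelp + (1 - f) * water + e` for the kelp fraction `f` by least
#' squares. The closed-form solution
#' `f = <r - w, k - w> / <k - w, k - w>` is clipped to \[0, 1\] (fractions
#' are physical proportions) and the RMSE is evaluated at the clipped `f`
#' over all bands, unweighted.
#'
#' @param reflectance Observed pixel spectrum.
#' @param kelp Kelp endmember spectrum.
#' @param water Seawater endmember spectrum.
#' @return A list with `fraction` and `rmse`.
#' @examples
#' unmix_pixel(c(0.1, 0.2), kelp = c(0, 0.4), water = c(0.2, 0))
#' @export
unmix_pixel <- function(reflectance, kelp, water) {
  reflectance <- check_spectrum(reflectance, "reflectance")
  kelp <- check_spectrum(kelp, "kelp", n_bands = length(reflectance))
  water <- check_spectrum(water, "water", n_bands = length(reflectance))
  d <- kelp - water
  dd <- sum(d * d)
  if (dd == 0) abort("Degenerate endmembers: kelp and water spectra are identical.")
  f <- sum((reflectance - water) * d) / dd
  f <- min(1, max(0, f))
  resid <- reflectance - (f * kelp + (1 - f) * water)
  list(fraction = f, rmse = sqrt(mean(resid^2)))
}

#' Unmix a full scene against a dynamic endmember library
#'
#' For every unmasked pixel, fits the two-endmember mixing model against each
#' seawater endmember in the library and keeps the candidate with the lowest
#' RMSE (ties broken by lowest endmember index, for determinism). Cloud-masked
#' pixels carry no fraction.
#'
#' @param scene An `n_rows x n_cols x n_bands` reflectance array (one entry
#'   of a `scene_stack`).
#' @param library An [sim_endmember_library()] result.
#' @param cloud_mask Optional logical matrix, `TRUE` = obscured.
#' @param date Optional acquisition date stored on the result.
#' @return A `fraction_map`: list with matrices `fraction` (NA where masked),
#'   `rmse`, `endmember` (chosen seawater index), logical `valid`, and `date`.
#' @export
unmix_scene <- function(scene, library, cloud_mask = NULL, date = NULL) {
  scene <- as.array(scene)
  if (length(dim(scene)) != 3L) abort("`scene` must be a rows x cols x bands array.")
  nr <- dim(scene)[1]; nc <- dim(scene)[2]; nb <- dim(scene)[3]
  validate_library(library, n_bands = nb)
  if (is.null(cloud_mask)) cloud_mask <- matrix(FALSE, nr, nc)
  if (!is.logical(cloud_mask) || !all(dim(cloud_mask) == c(nr, nc))) {
    abort("`cloud_mask` must be a logical matrix conformal with the scene.")
  }

  npix <- nr * nc
  R <- matrix(scene, npix, nb)          # pixels x bands
  kelp <- library$kelp
  K <- nrow(library$water)

  best_rmse <- rep(Inf, npix)
  best_f <- rep(NA_real_, npix)
  best_k <- rep(NA_integer_, npix)
  for (k in seq_len(K)) {
    w <- library$water[k, ]
    d <- kelp - w
    dd <- sum(d * d)
    if (dd == 0) abort("Degenerate endmembers: kelp equals a seawater spectrum.")
    f <- (R %*% d - sum(w * d))[, 1] / dd
    f <- pmin(1, pmax(0, f))
    model <- f %o% kelp + (1 - f) %o% w
    rmse <- sqrt(rowMeans((R - model)^2))
    better <- rmse < best_rmse          # strict: ties keep the lower index
    best_rmse[better] <- rmse[better]
    best_f[better] <- f[better]
    best_k[better] <- k
  }

  masked <- as.logical(cloud_mask)
  best_f[masked] <- NA_real_
  best_rmse[masked] <- NA_real_
  best_k[masked] <- NA_integer_

  structure(
    list(fraction = matrix(best_f, nr, nc),
         rmse = matrix(best_rmse, nr, nc),
         endmember = matrix(best_k, nr, nc),
         valid = matrix(!masked, nr, nc),
         date = date),
    class = "fraction_map"
  )
}

#' Unmix every scene of a stack
#'
#' @param stack A `scene_stack` from [sim_scene_series()] or
#'   [read_scene_stack()].
#' @param library An [sim_endmember_library()] result.
#' @return A list of `fraction_map` objects, one per date, carrying the
#'   stack's grid metadata as attributes.
#' @export
unmix_stack <- function(stack, library) {
  if (!inherits(stack, "scene_stack")) abort("`stack` must be a scene_stack.")
  maps <- purrr::map2(stack$scenes, seq_along(stack$dates), function(sc, i) {
    unmix_scene(sc, library, cloud_mask = stack$cloud[[i]], date = stack$dates[i])
  })
  attr(maps, "pixel_size") <- stack$pixel_size
  attr(maps, "n_rows") <- stack$n_rows
  attr(maps, "n_cols") <- stack$n_cols
  maps
}

#' @export
print.fraction_map <- function(x, ...) {
  cat(sprintf("<fraction_map> %dx%d pixels, %d valid, date %s\n",
              nrow(x$fraction), ncol(x$fraction), sum(x$valid),
              if (is.null(x$date)) "NA" else format(x$date)))
  invisible(x)
}

#' Filter acquisition dates by site-level cloud cover
#'
#' A date is removed when strictly more than `threshold` (default 25%) of the
#' pixels belonging to a site are obscured by clouds; a date at exactly the
#' threshold is retained.
#'
#' @param maps List of `fraction_map` objects.
#' @param site_pixels Integer vector of pixel indices (column-major into the
#'   fraction matrix) defining the site.
#' @param threshold Maximum tolerated obscured proportion (default 0.25).
#' @return A tibble with one row per date: `date`, `map_index`,
#'   `n_site_pixels`, `n_obscured`, `prop_obscured`, `retained`.
#' @export
site_cloud_filter <- function(maps, site_pixels, threshold = 0.25) {
  if (length(site_pixels) == 0L) abort("`site_pixels` must be non-empty.")
  threshold <- check_number(threshold, "threshold", min = 0, max = 1)
  purrr::map_dfr(seq_along(maps), function(i) {
    m <- maps[[i]]
    obscured <- sum(!m$valid[site_pixels])
    prop <- obscured / length(site_pixels)
    tibble::tibble(
      date = if (is.null(m$date)) as.Date(NA) else as.Date(m$date),
      map_index = i,
      n_site_pixels = length(site_pixels),
      n_obscured = obscured,
      prop_obscured = prop,
      retained = prop <= threshold
    )
  })
}
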