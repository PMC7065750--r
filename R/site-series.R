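#' Extract a site-level canopy time series from fraction maps
#'
#' Sums the kelp canopy fraction of all pixels whose centres lie within
#' `radius_m` of the site coordinates, for every acquisition date that passes
#' the site-level cloud filter (dates with more than `cloud_threshold` of the
#' site pixels obscured are removed). The default radius is 100 m; wider
#' ranges (400 m, 1000 m) can be set per site where few kelp pixels fall
#' within 100 m.
#'
#' Pixel geometry: pixel centres, row-major north-up grid with `x` increasing
#' eastward from the left edge and `y` northward from the bottom edge.
#'
#' @param maps List of `fraction_map` objects (e.g. from [unmix_stack()]).
#' @param site_coord Numeric `c(x, y)` site coordinates in metres.
#' @param radius_m Extraction radius in metres (default 100).
#' @param cloud_threshold Maximum obscured proportion tolerated per date
#'   (default 0.25, strictly-greater removal).
#' @param site_id Identifier stored in the output.
#' @param pixel_size Pixel size in metres; defaults to the stack attribute.
#' @return A tibble with `site_id`, `date`, `value` (summed fraction over
#'   valid site pixels) and `n_valid`; the site pixel indices and radius are
#'   attached as attributes.
#' @export
extract_site_series <- function(maps, site_coord, radius_m = 100,
                                cloud_threshold = 0.25, site_id = "site",
                                pixel_size = NULL) {
  if (length(maps) == 0L) abort("`maps` must be a non-empty list of fraction maps.")
  pixel_size <- pixel_size %||% attr(maps, "pixel_size") %||% 30
  radius_m <- check_number(radius_m, "radius_m", min = pixel_size / sqrt(2))

  nr <- nrow(maps[[1]]$fraction)
  nc <- ncol(maps[[1]]$fraction)
  idx <- site_pixel_indices(site_coord, nr, nc, pixel_size, radius_m)
  if (length(idx) == 0L) {
    abort(sprintf("Empty site: no pixel centres within %g m of (%g, %g).",
                  radius_m, site_coord[1], site_coord[2]))
  }

  filt <- site_cloud_filter(maps, idx, threshold = cloud_threshold)
  keep <- which(filt$retained)

  out <- purrr::map_dfr(keep, function(i) {
    m <- maps[[i]]
    vals <- m$fraction[idx]
    tibble::tibble(
      site_id = site_id,
      date = if (is.null(m$date)) as.Date(NA) else as.Date(m$date),
      value = sum(vals, na.rm = TRUE),
      n_valid = sum(!is.na(vals))
    )
  })
  attr(out, "site_pixels") <- idx
  attr(out, "radius_m") <- radius_m
  out
}

# Column-major indices of pixels whose centres fall within radius of (x, y).
site_pixel_indices <- function(site_coord, n_rows, n_cols, pixel_size, radius_m) {
  col <- rep(seq_len(n_cols), each = n_rows)
  row <- rep(seq_len(n_rows), times = n_cols)
  cx <- (col - 0.5) * pixel_size
  cy <- (n_rows - row + 0.5) * pixel_size
  d2 <- (cx - site_coord[1])^2 + (cy - site_coord[2])^2
  which(d2 <= radius_m^2)
}

#' Validate canopy fraction retrievals against in-situ kelp densities
#'
#' For each survey site, averages the canopy fraction of the four Landsat
#' pixels surrounding the site coordinate (the four pixel centres nearest to
#' the point) over all supplied maps, then fits a reduced major axis
#' regression of mean fraction on in-situ adult kelp density. Sites can be
#' excluded a priori (e.g. low geographic precision), and sites without any
#' kelp signal within `search_radius_m` (default 500 m) are dropped, since
#' terrain-shadowed shores defeat satellite retrieval.
#'
#' @param maps List of `fraction_map` objects.
#' @param sites Tibble with columns `site_id`, `x`, `y` (metres).
#' @param insitu Tibble with columns `site_id` and `adult_density`.
#' @param exclude Character vector of site ids to drop a priori.
#' @param search_radius_m Radius used for the kelp-presence screen.
#' @param pixel_size Pixel size in metres; defaults to the stack attribute.
#' @return A `kelp_validation` list: `sites` (per-site tibble with
#'   `mean_fraction`, `used`, `reason`) and `rma` (the [rma_fit()] result).
#' @export
validate_fraction_vs_insitu <- function(maps, sites, insitu, exclude = NULL,
                                        search_radius_m = 500,
                                        pixel_size = NULL) {
  pixel_size <- pixel_size %||% attr(maps, "pixel_size") %||% 30
  if (!all(c("site_id", "x", "y") %in% names(sites))) {
    abort("`sites` needs columns site_id, x, y.")
  }
  if (!all(c("site_id", "adult_density") %in% names(insitu))) {
    abort("`insitu` needs columns site_id and adult_density.")
  }
  nr <- nrow(maps[[1]]$fraction)
  nc <- ncol(maps[[1]]$fraction)

  per_site <- purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    reason <- NA_character_
    mean_frac <- NA_real_
    if (s$site_id %in% exclude) {
      reason <- "excluded a priori"
    } else {
      idx4 <- nearest_pixel_indices(c(s$x, s$y), nr, nc, pixel_size, k = 4L)
      vals <- purrr::map_dbl(maps, function(m) mean(m$fraction[idx4], na.rm = TRUE))
      mean_frac <- mean(vals, na.rm = TRUE)
      near <- site_pixel_indices(c(s$x, s$y), nr, nc, pixel_size, search_radius_m)
      has_kelp <- any(purrr::map_lgl(maps, function(m) {
        any(m$fraction[near] > 0, na.rm = TRUE)
      }))
      if (!has_kelp) reason <- sprintf("no kelp pixels within %g m", search_radius_m)
    }
    tibble::tibble(site_id = s$site_id, mean_fraction = mean_frac,
                   used = is.na(reason), reason = reason)
  })

  joined <- dplyr::inner_join(per_site, insitu, by = "site_id") |>
    dplyr::filter(.data$used)
  if (nrow(joined) < 3L) {
    abort("Fewer than 3 usable sites remain for the validation regression.")
  }
  rma <- rma_fit(joined$adult_density, joined$mean_fraction)
  structure(list(sites = per_site, data = joined, rma = rma),
            class = "kelp_validation")
}

nearest_pixel_indices <- function(coord, n_rows, n_cols, pixel_size, k = 4L) {
  col <- rep(seq_len(n_cols), each = n_rows)
  row <- rep(seq_len(n_rows), times = n_cols)
  cx <- (col - 0.5) * pixel_size
  cy <- (n_rows - row + 0.5) * pixel_size
  d2 <- (cx - coord[1])^2 + (cy - coord[2])^2
  order(d2)[seq_len(min(k, length(d2)))]
}
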