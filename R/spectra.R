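#' Simulate an endmember library of kelp and seawater spectra
#'
#' Builds the spectral library used by the two-endmember mixing model: one
#' static kelp-canopy endmember plus `n_water` seawater endmembers. The kelp
#' spectrum has the classic vegetation shape (low visible reflectance, strong
#' near-infrared plateau); seawater spectra are dark across all bands with
#' randomized visible-band variation emulating changing water conditions
#' (phytoplankton, suspended sediment, sunglint) between image dates. Band
#' order follows the Landsat reflective convention
#' (blue, green, red, NIR, SWIR1, SWIR2); other band counts are interpolated
#' from the same canonical shapes.
#'
#' @param n_water Number of seawater endmembers (default 30, the standard
#'   dynamic-library size for per-image seawater variability).
#' @param n_bands Number of reflective bands (default 6).
#' @param seed Integer seed; the library is a pure function of its arguments.
#' @param min_angle Minimum spectral angle (radians) required between the kelp
#'   endmember and every seawater endmember; generation errors if violated.
#'
#' @return An object of class `endmember_library`: a list with `kelp`
#'   (numeric length `n_bands`) and `water` (matrix `n_water` x `n_bands`).
#' @examples
#' lib <- sim_endmember_library(n_water = 30, n_bands = 6, seed = 1)
#' nrow(lib$water)
#' @export
sim_endmember_library <- function(n_water = 30, n_bands = 6, seed = 1,
                                  min_angle = 0.15) {
  n_water <- check_count(n_water, "n_water", min = 1L)
  n_bands <- check_count(n_bands, "n_bands", min = 2L)
  seed <- check_count(seed, "seed", min = 0L)
  min_angle <- check_number(min_angle, "min_angle", min = 0)

  # canonical 6-band shapes (blue..SWIR2), reflectance units
  kelp6 <- c(0.030, 0.045, 0.035, 0.320, 0.120, 0.060)
  water6 <- c(0.055, 0.045, 0.025, 0.008, 0.004, 0.002)
  grid6 <- seq(0, 1, length.out = 6L)
  grid <- seq(0, 1, length.out = n_bands)
  kelp <- approx(grid6, kelp6, xout = grid)$y
  wbase <- approx(grid6, water6, xout = grid)$y

  # visible-band weights: perturbations act mostly on the short-wave end
  vis_w <- pmax(0, 1 - grid / 0.6)

  water <- with_seed(seed, {
    t(vapply(seq_len(n_water), function(i) {
      shift <- rnorm(1L, mean = 0, sd = 0.010)      # overall brightness
      tilt <- rnorm(n_bands, mean = 0, sd = 0.006)  # band-wise variation
      pmax(wbase + vis_w * (shift + tilt), 1e-4)
    }, numeric(n_bands)))
  })

  angles <- apply(water, 1L, function(w) spectral_angle(kelp, w))
  if (any(angles <= min_angle)) {
    abort("Generated seawater spectra violate the kelp/water separation floor.")
  }

  structure(
    list(kelp = kelp, water = water, n_bands = n_bands, seed = seed),
    class = "endmember_library"
  )
}

#' Spectral angle between two spectra
#'
#' The angle (radians) between two reflectance vectors,
#' `acos(<a, b> / (|a| |b|))`; 0 means identical shape.
#'
#' @param a,b Numeric spectra of equal length.
#' @return Angle in radians.
#' @export
spectral_angle <- function(a, b) {
  a <- check_spectrum(a, "a")
  b <- check_spectrum(b, "b", n_bands = length(a))
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(1, max(-1, cosang)))
}

#' @export
print.endmember_library <- function(x, ...) {
  cat(sprintf("<endmember_library> 1 kelp + %d seawater spectra, %d bands\n",
              nrow(x$water), x$n_bands))
  invisible(x)
}

validate_library <- function(library, n_bands = NULL) {
  if (!inherits(library, "endmember_library")) {
    abort("`library` must be an `endmember_library` (see sim_endmember_library()).")
  }
  if (nrow(library$water) < 1L) abort("Endmember library has no seawater spectra.")
  if (!is.null(n_bands) && library$n_bands != n_bands) {
    abort(sprintf("Library has %d bands but the scene has %d.",
                  library$n_bands, n_bands))
  }
  invisible(library)
}
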