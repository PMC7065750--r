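#' Scene, fraction-map and table I/O
#'
#' Rasters are exchanged as plain-text long-format tables plus a YAML grid
#' header: `meta.yaml` records the grid (`n_rows`, `n_cols`, `n_bands`,
#' `pixel_size`, `dates`) and `scenes.csv` holds one row per
#' (date, row, col, band) with the reflectance value; cloud-obscured pixels
#' carry `NA` in every band (the nodata convention). Fraction maps use the
#' same layout with `fraction` and `rmse` columns. The format is
#' self-describing, diff-able and round-trips bit-exactly for double
#' precision values.
#'
#' @name kelp_io
NULL

# Bit-exact CSV round-trips for double columns: print with 17 significant
# digits and parse with strtod (base read.csv); the general-purpose readers
# (readr/vroom) trade the last couple of bits for speed.
write_csv_precise <- function(df, path) {
  df <- as.data.frame(df)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- sprintf("%.17g", df[[nm]])
      v[is.na(df[[nm]])] <- "NA"
      df[[nm]] <- v
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_csv_precise <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a scene stack to a directory
#'
#' @param stack A `scene_stack`.
#' @param dir Output directory (created if needed).
#' @param truth Also write the true fraction field if present (default TRUE).
#' @return `dir`, invisibly.
#' @export
write_scene_stack <- function(stack, dir, truth = TRUE) {
  if (!inherits(stack, "scene_stack")) abort("`stack` must be a scene_stack.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(
    list(n_rows = stack$n_rows, n_cols = stack$n_cols, n_bands = stack$n_bands,
         pixel_size = stack$pixel_size, dates = format(stack$dates)),
    file.path(dir, "meta.yaml")
  )
  long <- purrr::map_dfr(seq_along(stack$dates), function(i) {
    sc <- stack$scenes[[i]]
    cloud <- as.logical(stack$cloud[[i]])
    df <- tidyr::expand_grid(band = seq_len(stack$n_bands),
                             col = seq_len(stack$n_cols),
                             row = seq_len(stack$n_rows)) |>
      dplyr::arrange(.data$band, .data$col, .data$row)
    vals <- as.numeric(sc)
    vals[rep(cloud, times = stack$n_bands)] <- NA_real_
    tibble::tibble(date = format(stack$dates[i]), row = df$row, col = df$col,
                   band = df$band, value = vals)
  })
  write_csv_precise(long, file.path(dir, "scenes.csv"))
  if (truth && !is.null(stack$truth)) {
    tl <- purrr::map_dfr(seq_along(stack$dates), function(i) {
      tibble::tibble(date = format(stack$dates[i]),
                     row = rep(seq_len(stack$n_rows), times = stack$n_cols),
                     col = rep(seq_len(stack$n_cols), each = stack$n_rows),
                     fraction = as.numeric(stack$truth[[i]]))
    })
    write_csv_precise(tl, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

#' Read a scene stack from a directory
#'
#' @param dir Directory written by [write_scene_stack()].
#' @return A `scene_stack`; pixels that are `NA` in every band become cloud
#'   mask entries. Scenes whose pixel grid does not match the declared grid
#'   raise a grid-mismatch error.
#' @export
read_scene_stack <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  long <- read_csv_precise(file.path(dir, "scenes.csv"))
  nr <- meta$n_rows; nc <- meta$n_cols; nb <- meta$n_bands
  dates <- as.Date(meta$dates)
  per_scene <- nr * nc * nb

  scenes <- vector("list", length(dates))
  cloud <- vector("list", length(dates))
  truth <- NULL
  for (i in seq_along(dates)) {
    sub <- dplyr::filter(long, .data$date == format(dates[i]))
    if (nrow(sub) != per_scene ||
        !setequal(unique(sub$row), seq_len(nr)) ||
        !setequal(unique(sub$col), seq_len(nc))) {
      abort(sprintf("Grid mismatch for date %s: expected a complete %dx%dx%d grid.",
                    format(dates[i]), nr, nc, nb))
    }
    sub <- dplyr::arrange(sub, .data$band, .data$col, .data$row)
    arr <- array(sub$value, dim = c(nr, nc, nb))
    cl <- apply(is.na(arr), c(1, 2), all)
    arr[is.na(arr)] <- 0
    scenes[[i]] <- arr
    cloud[[i]] <- cl
  }

  truth_path <- file.path(dir, "truth.csv")
  if (file.exists(truth_path)) {
    tl <- read_csv_precise(truth_path)
    truth <- lapply(seq_along(dates), function(i) {
      sub <- dplyr::filter(tl, .data$date == format(dates[i])) |>
        dplyr::arrange(.data$col, .data$row)
      matrix(sub$fraction, nr, nc)
    })
  }

  structure(
    list(scenes = scenes, cloud = cloud, truth = truth, dates = dates,
         n_rows = nr, n_cols = nc, n_bands = nb,
         pixel_size = meta$pixel_size, seed = NA_integer_),
    class = "scene_stack"
  )
}

#' Write fraction maps to a directory
#'
#' @param maps List of `fraction_map` objects (with dates).
#' @param dir Output directory.
#' @param pixel_size Stored in the metadata (defaults to the stack attribute).
#' @return `dir`, invisibly.
#' @export
write_fraction_maps <- function(maps, dir, pixel_size = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pixel_size <- pixel_size %||% attr(maps, "pixel_size") %||% 30
  nr <- nrow(maps[[1]]$fraction); nc <- ncol(maps[[1]]$fraction)
  yaml::write_yaml(
    list(n_rows = nr, n_cols = nc, pixel_size = pixel_size,
         dates = purrr::map_chr(maps, function(m) format(as.Date(m$date)))),
    file.path(dir, "meta.yaml")
  )
  long <- purrr::map_dfr(maps, function(m) {
    tibble::tibble(date = format(as.Date(m$date)),
                   row = rep(seq_len(nr), times = nc),
                   col = rep(seq_len(nc), each = nr),
                   fraction = as.numeric(m$fraction),
                   rmse = as.numeric(m$rmse))
  })
  write_csv_precise(long, file.path(dir, "fractions.csv"))
  invisible(dir)
}

#' Read fraction maps from a directory
#'
#' @param dir Directory written by [write_fraction_maps()].
#' @return List of `fraction_map` objects with grid attributes.
#' @export
read_fraction_maps <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  long <- read_csv_precise(file.path(dir, "fractions.csv"))
  nr <- meta$n_rows; nc <- meta$n_cols
  maps <- lapply(meta$dates, function(d) {
    sub <- dplyr::filter(long, .data$date == d) |>
      dplyr::arrange(.data$col, .data$row)
    if (nrow(sub) != nr * nc) {
      abort(sprintf("Grid mismatch for date %s in fraction maps.", d))
    }
    fr <- matrix(sub$fraction, nr, nc)
    structure(list(fraction = fr, rmse = matrix(sub$rmse, nr, nc),
                   endmember = NULL, valid = !is.na(fr), date = as.Date(d)),
              class = "fraction_map")
  })
  attr(maps, "pixel_size") <- meta$pixel_size
  attr(maps, "n_rows") <- nr
  attr(maps, "n_cols") <- nc
  maps
}

#' Read long-format survey tables
#'
#' Pivots a long transect count file (columns `site`, `transect`, `taxon`,
#' `count`, `area_m2`) to a wide samples x taxa density table
#' (`density = count / area_m2`; taxa absent from a transect become
#' structural zeros) and joins the per-site factor table (columns `site`,
#' `location` in IE/MP, `exposure` in exposed/sheltered).
#'
#' @param path_counts CSV of long-format counts.
#' @param path_factors CSV of site factors.
#' @return A list with `abundance` (tibble: `sample_id` + taxa densities)
#'   and `factors` (tibble: `sample_id`, `site`, `location`, `exposure`).
#' @export
read_survey_tables <- function(path_counts, path_factors) {
  counts <- readr::read_csv(path_counts, progress = FALSE, show_col_types = FALSE)
  facs <- readr::read_csv(path_factors, progress = FALSE, show_col_types = FALSE)
  need <- c("site", "transect", "taxon", "count", "area_m2")
  if (!all(need %in% names(counts))) {
    abort(sprintf("Counts file needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (!all(c("site", "location", "exposure") %in% names(facs))) {
    abort("Factors file needs columns site, location, exposure.")
  }
  key <- paste(counts$site, counts$transect, counts$taxon, sep = "/")
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate (site, transect, taxon) rows: %s.",
                  key[which(duplicated(key))[1]]))
  }
  bad_loc <- setdiff(unique(facs$location), c("IE", "MP"))
  bad_exp <- setdiff(unique(facs$exposure), c("exposed", "sheltered"))
  if (length(bad_loc)) abort(sprintf("Unknown location level: %s.", bad_loc[1]))
  if (length(bad_exp)) abort(sprintf("Unknown exposure level: %s.", bad_exp[1]))

  abundance <- counts |>
    dplyr::mutate(sample_id = paste(.data$site, .data$transect, sep = "_"),
                  density = .data$count / .data$area_m2) |>
    dplyr::select("sample_id", "taxon", "density") |>
    tidyr::pivot_wider(names_from = "taxon", values_from = "density",
                       values_fill = 0)

  factors <- counts |>
    dplyr::distinct(.data$site, .data$transect) |>
    dplyr::mutate(sample_id = paste(.data$site, .data$transect, sep = "_")) |>
    dplyr::left_join(facs, by = "site")
  if (anyNA(factors$location) || anyNA(factors$exposure)) {
    abort("Some surveyed sites are missing from the factor table.")
  }
  list(abundance = abundance,
       factors = dplyr::select(factors, "sample_id", "site", "location", "exposure"))
}

#' Read a climate index series
#'
#' @param path CSV with columns `date` and `value`.
#' @return Tibble with `date` (Date) and `value`.
#' @export
read_climate_csv <- function(path) {
  df <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  if (!all(c("date", "value") %in% names(df))) {
    abort("Climate file needs columns date and value.")
  }
  dplyr::mutate(df, date = as.Date(.data$date))
}

#' Write a trimester series as CSV
#'
#' @param ts Trimester-series tibble.
#' @param path Output CSV path (columns `trimester_start_date`, `value`,
#'   `n_obs`).
#' @return `path`, invisibly.
#' @export
write_trimester_series <- function(ts, path) {
  readr::write_csv(
    tibble::tibble(trimester_start_date = ts$date, value = ts$value,
                   n_obs = ts$n_obs),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a trimester series CSV
#'
#' @param path CSV written by [write_trimester_series()].
#' @return A trimester-series tibble.
#' @export
read_trimester_series <- function(path) {
  df <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  out <- tibble::tibble(
    trimester = seq_len(nrow(df)),
    date = as.Date(df$trimester_start_date),
    value = df$value,
    n_obs = as.integer(df$n_obs)
  )
  class(out) <- c("trimester_series", class(out))
  out
}
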