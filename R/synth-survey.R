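#' Specify a factorial community survey simulation
#'
#' Describes transect-level invertebrate/fish count tables from a 2x2
#' location (IE, MP) by exposure (exposed, sheltered) design. Counts per
#' transect are negative binomial with log-scale multiplicative factor
#' effects, matching the character of real survey tables (non-negative,
#' overdispersed, means with large standard deviations).
#'
#' @param n_sites_per_cell Samples per design cell, either a single count or
#'   a length-4 vector ordered IE/exposed, IE/sheltered, MP/exposed,
#'   MP/sheltered. The default `c(5, 5, 4, 4)` gives the 18-station design.
#' @param taxa_pool Tibble with columns `taxon` and `baseline` (mean count
#'   per transect). Defaults to a 12-taxon pool spanning dominant barnacles
#'   through rare sea stars.
#' @param effect_sizes Tibble with columns `taxon`, `factor`
#'   (`"location"` or `"exposure"`), `level`, and `multiplier`: the mean of
#'   that taxon is multiplied by `multiplier` in samples at that level.
#'   `NULL` (default) means no effects (a null community).
#' @param dispersion Negative binomial size parameter (smaller = more
#'   overdispersed; default 1.5).
#' @param transect_area Transect area in square metres (default 50).
#' @param seed Integer seed.
#' @return A `survey_spec` list.
#' @export
survey_spec <- function(n_sites_per_cell = c(5, 5, 4, 4), taxa_pool = NULL,
                        effect_sizes = NULL, dispersion = 1.5,
                        transect_area = 50, seed = 1) {
  if (length(n_sites_per_cell) == 1L) n_sites_per_cell <- rep(n_sites_per_cell, 4L)
  if (length(n_sites_per_cell) != 4L) {
    abort("`n_sites_per_cell` must have length 1 or 4.")
  }
  n_sites_per_cell <- vapply(seq_along(n_sites_per_cell), function(i) {
    check_count(n_sites_per_cell[i], "n_sites_per_cell", min = 1L)
  }, integer(1))
  dispersion <- check_number(dispersion, "dispersion", min = 1e-6)
  transect_area <- check_number(transect_area, "transect_area", min = 1e-6)
  seed <- check_count(seed, "seed", min = 0L)

  if (is.null(taxa_pool)) {
    taxa_pool <- tibble::tibble(
      taxon = c("barnacle_dom", "urchin_chilean", "bryozoan_encr",
                "anemone_oct", "ascidian_a", "ascidian_b", "bivalve_frond",
                "seastar_cind", "urchin_small", "gastropod_marg",
                "hermit_crab", "holothurian"),
      baseline = c(300, 65, 80, 48, 37, 30, 70, 16, 18, 22, 12, 8)
    )
  }
  taxa_pool <- tibble::as_tibble(taxa_pool)
  if (nrow(taxa_pool) == 0L) abort("`taxa_pool` must contain at least one taxon.")
  if (!all(c("taxon", "baseline") %in% names(taxa_pool))) {
    abort("`taxa_pool` needs columns `taxon` and `baseline`.")
  }
  if (any(taxa_pool$baseline < 0)) abort("Baseline means must be >= 0.")
  if (anyDuplicated(taxa_pool$taxon)) abort("Duplicate taxa in `taxa_pool`.")

  if (!is.null(effect_sizes)) {
    effect_sizes <- tibble::as_tibble(effect_sizes)
    need <- c("taxon", "factor", "level", "multiplier")
    if (!all(need %in% names(effect_sizes))) {
      abort("`effect_sizes` needs columns taxon, factor, level, multiplier.")
    }
    if (!all(effect_sizes$factor %in% c("location", "exposure"))) {
      abort("`effect_sizes$factor` must be 'location' or 'exposure'.")
    }
    if (any(effect_sizes$multiplier <= 0)) abort("Multipliers must be > 0.")
  }

  structure(
    list(n_sites_per_cell = n_sites_per_cell, taxa_pool = taxa_pool,
         effect_sizes = effect_sizes, dispersion = dispersion,
         transect_area = transect_area, seed = seed),
    class = "survey_spec"
  )
}

#' Generate factorial community abundance and factor tables
#'
#' Draws negative binomial counts for every sample x taxon combination of a
#' [survey_spec()] and converts them to densities (individuals per square
#' metre) by dividing by the transect area.
#'
#' @param spec A [survey_spec()].
#' @return A list with `abundance` (tibble: `sample_id` + one density column
#'   per taxon), `counts` (same shape, raw counts), and `factors` (tibble:
#'   `sample_id`, `location`, `exposure`).
#' @examples
#' tabs <- sim_survey_tables(survey_spec(seed = 3))
#' dim(tabs$abundance)
#' @export
sim_survey_tables <- function(spec) {
  if (!inherits(spec, "survey_spec")) abort("`spec` must be a survey_spec().")
  cells <- tibble::tibble(
    location = c("IE", "IE", "MP", "MP"),
    exposure = c("exposed", "sheltered", "exposed", "sheltered"),
    n = spec$n_sites_per_cell
  )
  factors <- tidyr::uncount(cells, .data$n) |>
    dplyr::mutate(sample_id = sprintf("s%02d", dplyr::row_number()),
                  .before = 1)

  taxa <- spec$taxa_pool$taxon
  base <- spec$taxa_pool$baseline
  nsamp <- nrow(factors)

  # per-sample, per-taxon expected counts with multiplicative factor effects
  mu <- matrix(rep(base, each = nsamp), nrow = nsamp,
               dimnames = list(factors$sample_id, taxa))
  if (!is.null(spec$effect_sizes)) {
    for (i in seq_len(nrow(spec$effect_sizes))) {
      ef <- spec$effect_sizes[i, ]
      rows <- factors[[ef$factor]] == ef$level
      mu[rows, ef$taxon] <- mu[rows, ef$taxon] * ef$multiplier
    }
  }

  counts <- with_seed(spec$seed, {
    matrix(rnbinom(length(mu), mu = as.numeric(mu), size = spec$dispersion),
           nrow = nsamp, dimnames = dimnames(mu))
  })

  counts_tbl <- tibble::as_tibble(counts) |>
    dplyr::mutate(sample_id = factors$sample_id, .before = 1)
  abund_tbl <- tibble::as_tibble(counts / spec$transect_area) |>
    dplyr::mutate(sample_id = factors$sample_id, .before = 1)

  list(abundance = abund_tbl, counts = counts_tbl, factors = factors)
}
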