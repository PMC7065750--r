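#' ln(x+1) transform an abundance table
#'
#' The standard compression applied to community density tables before
#' computing Bray-Curtis dissimilarities, damping the influence of
#' numerically dominant taxa.
#'
#' @param abundance Tibble with a `sample_id` column plus one non-negative
#'   numeric column per taxon (or a plain numeric matrix).
#' @return The same shape with every abundance replaced by `log(x + 1)`.
#' @export
ln1p_transform <- function(abundance) {
  m <- abundance_matrix(abundance)
  if (any(m < 0)) abort("Abundances must be non-negative.")
  lg <- log1p(m)
  if (is.data.frame(abundance)) {
    abundance[, colnames(m)] <- tibble::as_tibble(lg)
    abundance
  } else {
    lg
  }
}

# Coerce a sample_id-keyed tibble or matrix to a numeric samples x taxa matrix
abundance_matrix <- function(abundance) {
  if (is.data.frame(abundance)) {
    ids <- if ("sample_id" %in% names(abundance)) abundance$sample_id else
      as.character(seq_len(nrow(abundance)))
    num <- abundance[setdiff(names(abundance), "sample_id")]
    if (!all(vapply(num, is.numeric, logical(1)))) {
      abort("All taxon columns must be numeric.")
    }
    m <- as.matrix(num)
    rownames(m) <- ids
  } else {
    m <- as.matrix(abundance)
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("taxon", seq_len(ncol(m)))
  }
  if (anyDuplicated(rownames(m))) abort("Duplicate sample ids.")
  if (anyDuplicated(colnames(m))) abort("Duplicate taxon ids.")
  storage.mode(m) <- "double"
  m
}

#' Diversity metrics for a single sample
#'
#' Computes the classical suite from one vector of counts (or densities):
#' total taxa `S` (non-zero entries), total individuals `N`, Margalef
#' richness `d = (S - 1) / ln(N)`, Shannon-Wiener diversity
#' `H = -sum(p_i * ln(p_i))` in nats, and Pielou evenness `J = H / ln(S)`.
#' All logarithms are natural. `J` is reported missing for a monoculture
#' (`S = 1`, where `ln(S) = 0`).
#'
#' @param sample Non-negative numeric vector of counts for one sample.
#' @return A one-row tibble: `S`, `N`, `d`, `H`, `J`.
#' @examples
#' diversity_metrics(c(5, 5, 10))
#' @export
diversity_metrics <- function(sample) {
  x <- as.numeric(sample)
  if (anyNA(x) || any(x < 0)) abort("Counts must be non-negative and non-missing.")
  if (sum(x) == 0) abort("All-zero sample: diversity is undefined.")
  x <- x[x > 0]
  S <- length(x)
  N <- sum(x)
  p <- x / N
  H <- -sum(p * log(p))
  tibble::tibble(
    S = S,
    N = N,
    d = if (N > 1) (S - 1) / log(N) else 0,
    H = H,
    J = if (S > 1) H / log(S) else NA_real_
  )
}

#' Diversity metrics for every sample of an abundance table
#'
#' @param abundance Samples x taxa tibble (with `sample_id`) or matrix.
#' @return A tibble with one row per sample: `sample_id`, `S`, `N`, `d`,
#'   `H`, `J`.
#' @export
diversity_table <- function(abundance) {
  m <- abundance_matrix(abundance)
  purrr::map_dfr(seq_len(nrow(m)), function(i) {
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)[i]),
                     diversity_metrics(m[i, ]))
  })
}

#' Index of Relative Dominance
#'
#' `IRD = %num x %freq`: percent numerical abundance (the taxon's share of
#' total density across all samples, x100) multiplied by percent frequency
#' of occurrence (the share of samples in which the taxon is present, x100).
#' Reported rounded to the nearest integer alongside the unrounded value,
#' ranked in descending order. Computed on raw (untransformed) densities.
#'
#' @param abundance Samples x taxa tibble (with `sample_id`) or matrix of
#'   densities or counts.
#' @return A tibble ranked by IRD: `taxon`, `mean_density`, `sd_density`,
#'   `pct_num`, `pct_freq`, `ird`, `ird_raw`.
#' @examples
#' m <- rbind(a = c(10, 1, 0), b = c(8, 0, 2))
#' colnames(m) <- c("t1", "t2", "t3")
#' ird_table(m)
#' @export
ird_table <- function(abundance) {
  m <- abundance_matrix(abundance)
  if (nrow(m) < 1L || ncol(m) < 1L) abort("Need at least one sample and one taxon.")
  total <- sum(m)
  if (total == 0) abort("All abundances are zero.")
  pct_num <- 100 * colSums(m) / total
  pct_freq <- 100 * colMeans(m > 0)
  tibble::tibble(
    taxon = colnames(m),
    mean_density = colMeans(m),
    sd_density = apply(m, 2, sd),
    pct_num = unname(pct_num),
    pct_freq = unname(pct_freq),
    ird = ird_index(pct_num, pct_freq),
    ird_raw = unname(pct_num * pct_freq)
  ) |>
    dplyr::arrange(dplyr::desc(.data$ird_raw))
}

#' Combine dominance percentages into an IRD value
#'
#' The elementary IRD step: percent numerical abundance times percent
#' frequency of occurrence, rounded to the nearest integer (the convention
#' used in published dominance tables).
#'
#' @param pct_num Percent numerical abundance (0-100).
#' @param pct_freq Percent frequency of occurrence (0-100).
#' @return Integer-rounded IRD values.
#' @examples
#' ird_index(12.20, 77.78)
#' @export
ird_index <- function(pct_num, pct_freq) {
  if (any(pct_num < 0 | pct_num > 100, na.rm = TRUE) ||
      any(pct_freq < 0 | pct_freq > 100, na.rm = TRUE)) {
    abort("Percentages must lie in [0, 100].")
  }
  unname(round(pct_num * pct_freq))
}
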