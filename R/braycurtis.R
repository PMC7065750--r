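#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarities
#' `d(i, j) = sum(|x_ik - x_jk|) / sum(x_ik + x_jk)` between all sample rows
#' of an abundance table. This is the dissimilarity form (1 - similarity);
#' values lie in \[0, 1\], with 0 for identical composition and 1 for
#' disjoint taxa. Two all-zero samples are assigned distance 0 with a
#' warning (a documented convention; the ratio is otherwise 0/0).
#'
#' @param abundance Samples x taxa tibble (with `sample_id`) or matrix of
#'   non-negative abundances, typically [ln1p_transform()]ed densities.
#' @return A symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @examples
#' bray_curtis(rbind(a = c(1, 2, 0), b = c(0, 2, 4)))
#' @export
bray_curtis <- function(abundance) {
  m <- abundance_matrix(abundance)
  if (nrow(m) < 2L) abort("Need at least 2 samples.")
  if (any(m < 0)) abort("Abundances must be non-negative.")
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      denom <- sum(m[i, ] + m[j, ])
      if (denom == 0) {
        if (!warned) {
          warn("All-zero sample pair: Bray-Curtis distance set to 0 by convention.")
          warned <- TRUE
        }
        dij <- 0
      } else {
        dij <- sum(abs(m[i, ] - m[j, ])) / denom
      }
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

# Coerce dist / matrix input to a validated square dissimilarity matrix
as_distance_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) abort("Distance matrix must be square.")
  if (max(abs(d - t(d))) > 1e-8) abort("Distance matrix must be symmetric.")
  if (any(abs(diag(d)) > 1e-8)) abort("Distance matrix must have a zero diagonal.")
  d
}

# Gower-centered inner-product matrix G = -1/2 * J A J with A = d^2
gower_center <- function(d) {
  a <- -0.5 * d^2
  n <- nrow(a)
  rm <- rowMeans(a)
  a - matrix(rm, n, n) - matrix(rm, n, n, byrow = TRUE) + mean(a)
}
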