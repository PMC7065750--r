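#' Principal coordinates analysis
#'
#' Metric multidimensional scaling: eigen-decomposition of the Gower-centered
#' dissimilarity matrix. Sample coordinates are the eigenvectors scaled by
#' the square root of their (positive) eigenvalues; negative eigenvalues --
#' expected for non-Euclidean dissimilarities like Bray-Curtis -- are
#' retained and reported but excluded from the coordinates. Percent
#' variation per axis uses positive eigenvalues only (no correction by
#' default; Lingoes correction available).
#'
#' @param d Square dissimilarity matrix or `dist`.
#' @param correction `"none"` (default) or `"lingoes"` (adds the constant
#'   that makes all eigenvalues non-negative before re-decomposing).
#' @return A `kelp_pco` object: `points` (samples x axes), `eigenvalues`
#'   (all, descending), `percent_var` (per positive axis),
#'   `negative_eigenvalues` (logical), `correction`.
#' @examples
#' d <- as.matrix(dist(cbind(1:5)))
#' pco(d)$percent_var
#' @export
pco <- function(d, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < 3L) abort("Need at least 3 samples for an ordination.")

  G <- gower_center(d)
  eig <- eigen(G, symmetric = TRUE)
  if (correction == "lingoes" && min(eig$values) < -1e-8) {
    cc <- -min(eig$values)
    d2 <- d^2 + 2 * cc
    diag(d2) <- 0
    G <- gower_center(sqrt(d2))
    eig <- eigen(G, symmetric = TRUE)
  }

  vals <- eig$values
  tol <- max(abs(vals)) * 1e-8
  pos <- which(vals > tol)
  pts <- eig$vectors[, pos, drop = FALSE] %*% diag(sqrt(vals[pos]), length(pos))
  colnames(pts) <- paste0("Axis.", seq_along(pos))
  rownames(pts) <- rownames(d)

  structure(
    list(points = pts,
         eigenvalues = vals,
         percent_var = 100 * vals[pos] / sum(vals[pos]),
         negative_eigenvalues = any(vals < -tol),
         correction = correction),
    class = "kelp_pco"
  )
}

#' @export
print.kelp_pco <- function(x, ...) {
  cat(sprintf("PCO: %d samples, %d positive axes (Axis 1: %.1f%%)%s\n",
              nrow(x$points), ncol(x$points), x$percent_var[1],
              if (x$negative_eigenvalues) "; negative eigenvalues present" else ""))
  invisible(x)
}

#' Species vectors for a PCO ordination
#'
#' Pearson correlations of each taxon's abundance with the first two
#' ordination axes; taxa whose strongest axis correlation reaches the
#' threshold (default |r| >= 0.5) are retained as overlay vectors with
#' components `(r_axis1, r_axis2)`. Zero-variance taxa are excluded with a
#' warning.
#'
#' @param ordination A `kelp_pco` object.
#' @param abundance The abundance table the ordination was built from
#'   (row-aligned with the distance matrix).
#' @param threshold Minimum absolute correlation to retain (default 0.5).
#' @return Tibble with `taxon`, `r_axis1`, `r_axis2`, `r_max`.
#' @export
vector_overlay <- function(ordination, abundance, threshold = 0.5) {
  if (!inherits(ordination, "kelp_pco")) abort("`ordination` must be a kelp_pco.")
  threshold <- check_number(threshold, "threshold", min = 0, max = 1)
  m <- abundance_matrix(abundance)
  pts <- ordination$points
  if (nrow(m) != nrow(pts)) abort("Abundance rows do not match the ordination.")
  if (ncol(pts) < 2L) abort("Ordination has fewer than 2 positive axes.")
  if (!is.null(rownames(pts)) && all(rownames(pts) %in% rownames(m))) {
    m <- m[rownames(pts), , drop = FALSE]
  }

  keep_var <- apply(m, 2, var) > 0
  if (any(!keep_var)) {
    warn(sprintf("Excluding %d zero-variance taxa from the overlay.",
                 sum(!keep_var)))
  }
  m <- m[, keep_var, drop = FALSE]

  r1 <- apply(m, 2, cor, y = pts[, 1])
  r2 <- apply(m, 2, cor, y = pts[, 2])
  out <- tibble::tibble(
    taxon = colnames(m), r_axis1 = unname(r1), r_axis2 = unname(r2),
    r_max = pmax(abs(r1), abs(r2))
  )
  dplyr::filter(out, .data$r_max >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$r_max))
}
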