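#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a canopy fraction map
#'
#' @param map A `fraction_map`.
#' @param ... Unused.
#' @return A ggplot raster of the canopy fraction (masked pixels blank).
#' @export
plot_fraction_map <- function(map, ...) {
  if (!inherits(map, "fraction_map")) abort("`map` must be a fraction_map.")
  nr <- nrow(map$fraction)
  df <- tibble::tibble(
    row = rep(seq_len(nr), times = ncol(map$fraction)),
    col = rep(seq_len(ncol(map$fraction)), each = nr),
    fraction = as.numeric(map$fraction)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$fraction)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Canopy\nfraction",
                  title = if (is.null(map$date)) NULL else format(map$date)) +
    ggplot2::theme_minimal()
}

#' Plot a trimester series
#'
#' @param object A trimester-series tibble.
#' @param ... Unused.
#' @return A ggplot line plot; interpolated steps (`n_obs = 0`) are drawn as
#'   open points.
#' @exportS3Method ggplot2::autoplot
autoplot.trimester_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$n_obs > 0), size = 1.6) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                labels = c(`TRUE` = "observed",
                                           `FALSE` = "interpolated")) +
    ggplot2::labs(x = NULL, y = "Canopy density", shape = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a PCO ordination with species vectors
#'
#' @param object A `kelp_pco`.
#' @param factors Optional tibble with `sample_id`, `location`, `exposure`
#'   used for point colour/shape.
#' @param vectors Optional [vector_overlay()] tibble drawn as arrows.
#' @param ... Unused.
#' @return A ggplot ordination plot.
#' @exportS3Method ggplot2::autoplot
autoplot.kelp_pco <- function(object, factors = NULL, vectors = NULL, ...) {
  scores <- tidy(object)
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2))
  if (!is.null(factors)) {
    scores <- dplyr::left_join(scores, factors, by = "sample_id")
    p <- ggplot2::ggplot(scores,
                         ggplot2::aes(x = .data$Axis.1, y = .data$Axis.2,
                                      colour = .data$location,
                                      shape = .data$exposure))
  }
  p <- p + ggplot2::geom_point(size = 2.5)
  if (!is.null(vectors) && nrow(vectors) > 0) {
    sc <- max(abs(scores$Axis.1), abs(scores$Axis.2))
    p <- p +
      ggplot2::geom_segment(
        data = vectors, inherit.aes = FALSE,
        ggplot2::aes(x = 0, y = 0, xend = .data$r_axis1 * sc,
                     yend = .data$r_axis2 * sc),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
        colour = "grey30"
      ) +
      ggplot2::geom_text(
        data = vectors, inherit.aes = FALSE,
        ggplot2::aes(x = .data$r_axis1 * sc * 1.08,
                     y = .data$r_axis2 * sc * 1.08, label = .data$taxon),
        size = 2.8, colour = "grey30"
      )
  }
  p +
    ggplot2::labs(
      x = sprintf("PCO1 (%.1f%%)", object$percent_var[1]),
      y = sprintf("PCO2 (%.1f%%)",
                  if (length(object$percent_var) > 1) object$percent_var[2] else NA)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a lag-correlation scan
#'
#' @param scan A [lag_scan()] tibble.
#' @return A ggplot of r against lag with the |r|-maximizing lag marked.
#' @export
plot_lag_scan <- function(scan) {
  best <- scan$lag[which.max(abs(scan$r))]
  ggplot2::ggplot(scan, ggplot2::aes(x = .data$lag, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = best, linetype = 2, colour = "firebrick") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Lag (trimesters, driver leads)", y = "Pearson r") +
    ggplot2::theme_minimal()
}
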