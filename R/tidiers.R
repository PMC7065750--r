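#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for kelpcanopy result objects
#'
#' `tidy()` returns the per-term or per-axis table of a result;
#' `glance()` returns a one-row model summary.
#'
#' @param x A fitted kelpcanopy object.
#' @param ... Unused.
#' @name kelpcanopy-tidiers
NULL

#' @exportS3Method generics::tidy
#' @rdname kelpcanopy-tidiers
tidy.kelp_permanova <- function(x, ...) x$table

#' @exportS3Method generics::glance
#' @rdname kelpcanopy-tidiers
glance.kelp_permanova <- function(x, ...) {
  tibble::tibble(n = x$n, n_perm = x$n_perm,
                 min_p = min(x$table$p_perm, na.rm = TRUE))
}

#' @exportS3Method generics::tidy
#' @rdname kelpcanopy-tidiers
tidy.kelp_pco <- function(x, ...) {
  tibble::as_tibble(x$points, rownames = "sample_id")
}

#' @exportS3Method generics::glance
#' @rdname kelpcanopy-tidiers
glance.kelp_pco <- function(x, ...) {
  tibble::tibble(
    n_axes = ncol(x$points),
    pct_axis1 = x$percent_var[1],
    pct_axis2 = if (length(x$percent_var) > 1) x$percent_var[2] else NA_real_,
    negative_eigenvalues = x$negative_eigenvalues
  )
}

#' @exportS3Method generics::tidy
#' @rdname kelpcanopy-tidiers
tidy.kelp_lagcor <- function(x, ...) {
  tibble::tibble(lag = x$lag, r = x$r, p_value = x$p_value, n = x$n)
}

#' @exportS3Method generics::glance
#' @rdname kelpcanopy-tidiers
glance.kelp_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, se = x$se, rho = x$rho, t = x$t,
                 p_value = x$p_value, n = x$n, df = x$df)
}

#' @exportS3Method generics::tidy
#' @rdname kelpcanopy-tidiers
tidy.kelp_trend <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "trimester"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::tidy
#' @rdname kelpcanopy-tidiers
tidy.kelp_rma <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @exportS3Method generics::glance
#' @rdname kelpcanopy-tidiers
glance.kelp_rma <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 r_squared = x$r_squared, n = x$n)
}

#' @exportS3Method generics::glance
#' @rdname kelpcanopy-tidiers
glance.kelp_pillai <- function(x, ...) {
  tibble::tibble(pillai = x$pillai, F_approx = x$F_approx, df1 = x$df1,
                 df2 = x$df2, p_value = x$p_value, n = x$n)
}

#' @exportS3Method generics::glance
#' @rdname kelpcanopy-tidiers
glance.kelp_smooth <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, df = x$df, n = nrow(x$data))
}
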