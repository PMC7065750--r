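#' Pillai's-trace MANOVA
#'
#' One-way multivariate analysis of variance using Pillai's trace, the most
#' robust of the classical MANOVA statistics to heterogeneity of variance:
#' `V = sum(lambda_i / (1 + lambda_i))` over the eigenvalues of
#' `E^-1 H` (equivalently the sum of eigenvalues of `H (H + E)^-1`), with
#' the standard F approximation.
#'
#' @param y Numeric matrix or data frame of responses (samples x variables).
#' @param groups Grouping factor (>= 2 levels).
#' @return A `kelp_pillai` list: `pillai`, `F_approx`, `df1`, `df2`,
#'   `p_value`, `eigenvalues`.
#' @examples
#' pillai_manova(iris[, 1:4], iris$Species)
#' @export
pillai_manova <- function(y, groups) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  g <- factor(groups)
  n <- nrow(y); p <- ncol(y); k <- nlevels(g)
  if (k < 2L) abort("Need at least 2 groups.")
  if (length(g) != n) abort("`groups` must match the rows of `y`.")
  if (n <= p + k) abort("Need n > p + number of groups for the F approximation.")

  grand <- colMeans(y)
  H <- matrix(0, p, p)
  E <- matrix(0, p, p)
  for (lev in levels(g)) {
    yi <- y[g == lev, , drop = FALSE]
    ni <- nrow(yi)
    mi <- colMeans(yi)
    H <- H + ni * tcrossprod(mi - grand)
    cent <- sweep(yi, 2, mi)
    E <- E + crossprod(cent)
  }

  Einv <- tryCatch(solve(E), error = function(e) {
    abort("Error matrix E is singular: reduce or decorrelate the response variables.")
  })
  lambda <- Re(eigen(Einv %*% H, only.values = TRUE)$values)
  lambda <- pmax(lambda, 0)
  V <- sum(lambda / (1 + lambda))

  s <- min(p, k - 1L)
  m <- (abs(p - (k - 1L)) - 1) / 2
  nn <- (n - k - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  F_approx <- (df2 / df1) * (V / (s - V))
  p_value <- pf(F_approx, df1, df2, lower.tail = FALSE)

  structure(
    list(pillai = V, F_approx = F_approx, df1 = df1, df2 = df2,
         p_value = p_value, eigenvalues = lambda, n = n),
    class = "kelp_pillai"
  )
}

#' @export
print.kelp_pillai <- function(x, ...) {
  cat(sprintf("Pillai's trace = %.4f, F(%g, %g) = %.3f, p = %.4g\n",
              x$pillai, x$df1, x$df2, x$F_approx, x$p_value))
  invisible(x)
}

#' Paired t-test on site-matched values
#'
#' Standard paired t-test on the differences `after - before` (e.g. kelp
#' densities at the same sites across two survey eras). When all differences
#' are zero the statistic is 0 with p = 1 (a degenerate case the textbook
#' formula leaves undefined).
#'
#' @param before,after Numeric vectors of equal length (n >= 3).
#' @return Tibble with `t`, `df`, `p_value`, `mean_diff`, `n`.
#' @examples
#' paired_t(c(1, 2, 3), c(2, 4, 6))
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after)) abort("`before` and `after` differ in length.")
  ok <- !is.na(before) & !is.na(after)
  b <- as.numeric(before[ok]); a <- as.numeric(after[ok])
  n <- length(b)
  if (n < 3L) abort("Need at least 3 complete pairs.")
  d <- a - b
  if (sd(d) == 0) {
    tv <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    pv <- if (mean(d) == 0) 1 else 0
  } else {
    tt <- t.test(a, b, paired = TRUE)
    tv <- unname(tt$statistic)
    pv <- tt$p.value
  }
  tibble::tibble(t = tv, df = n - 1L, p_value = pv, mean_diff = mean(d), n = n)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t-test with pooled variance and a two-sided p-value. When the
#' pooled variance is zero and the means are equal, `t = 0` by convention;
#' zero pooled variance with unequal means is an error (the statistic is
#' undefined).
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return Tibble with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(a, b) {
  a <- as.numeric(na.omit(a)); b <- as.numeric(na.omit(b))
  if (length(a) < 2L || length(b) < 2L) abort("Each sample needs at least 2 values.")
  df <- length(a) + length(b) - 2L
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = df, p_value = 1,
                            mean_a = mean(a), mean_b = mean(b)))
    }
    abort("Zero pooled variance with unequal means: t is undefined.")
  }
  tt <- t.test(a, b, var.equal = TRUE)
  tibble::tibble(t = unname(tt$statistic), df = df, p_value = tt$p.value,
                 mean_a = mean(a), mean_b = mean(b))
}

#' Chi-square test of compositional homogeneity
#'
#' Pearson chi-square comparing the proportional contribution of each
#' category (e.g. sea urchin species) between groups, on a groups x
#' categories contingency table with `(rows - 1) * (cols - 1)` degrees of
#' freedom and no continuity correction.
#'
#' @param table Matrix of counts (e.g. 2 x k).
#' @return Tibble with `X2`, `df`, `p_value`.
#' @examples
#' chi_square_composition(rbind(c(10, 20), c(20, 10)))
#' @export
chi_square_composition <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || anyNA(tab)) abort("Counts must be non-negative and complete.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Zero marginal total: expected counts are undefined.")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(X2 = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value)
}
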