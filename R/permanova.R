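#' Two-way PERMANOVA with permutation of residuals under a reduced model
#'
#' Permutational multivariate analysis of variance on a dissimilarity matrix
#' for a two-factor crossed design with interaction. The distance matrix is
#' partitioned through its Gower-centered inner-product form
#' (McArdle-Anderson); sums of squares are Type III (partial), defined by
#' sum-to-zero contrasts, so each term is adjusted for all others including
#' the interaction. Significance for each term comes from permutation of
#' residuals under the reduced model (Freedman-Lane): residuals of the model
#' without the term are permuted, the reduced-model fit is added back, and
#' the pseudo-F is recomputed; `p = (b + 1) / (n_perm + 1)` where `b` counts
#' permuted statistics at or above the observed one.
#'
#' @param d Square dissimilarity matrix (or `dist`), e.g. [bray_curtis()].
#' @param factors Tibble with the factor columns named in `terms` (and
#'   optionally `sample_id` to align with the dimnames of `d`).
#' @param terms Character vector of the two factor column names
#'   (default `c("location", "exposure")`).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream (mandatory for
#'   reproducibility; default 1).
#' @return A `kelp_permanova` object; `tidy()` returns the ANOVA-style table
#'   with `term`, `df`, `SS`, `MS`, `pseudo_F`, `p_perm`.
#' @examples
#' tabs <- sim_survey_tables(survey_spec(seed = 1))
#' d <- bray_curtis(ln1p_transform(tabs$abundance))
#' permanova_2way(d, tabs$factors, n_perm = 99, seed = 1)
#' @export
permanova_2way <- function(d, factors, terms = c("location", "exposure"),
                           n_perm = 999, seed = 1) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (length(terms) != 2L || !all(terms %in% names(factors))) {
    abort("`terms` must name two factor columns present in `factors`.")
  }
  if (nrow(factors) != n) abort("`factors` must have one row per sample.")
  if ("sample_id" %in% names(factors) && !is.null(rownames(d))) {
    ord <- match(rownames(d), factors$sample_id)
    if (anyNA(ord)) abort("`factors$sample_id` does not cover the distance matrix.")
    factors <- factors[ord, ]
  }
  A <- factor(factors[[terms[1]]])
  B <- factor(factors[[terms[2]]])
  if (nlevels(A) < 2L || nlevels(B) < 2L) {
    abort("Each factor needs at least 2 levels.")
  }

  X <- stats::model.matrix(~ A * B,
                           contrasts.arg = list(A = "contr.sum", B = "contr.sum"))
  asgn <- attr(X, "assign")      # 0 = intercept, 1 = A, 2 = B, 3 = A:B
  if (qr(X)$rank < ncol(X)) {
    abort("Confounded design: a model term is inestimable (empty cell?).")
  }

  labels <- c(terms[1], terms[2], paste(terms, collapse = ":"))
  res <- permanova_engine(gower_center(d), X, asgn, term_ids = 1:3,
                          term_labels = labels, n_perm = n_perm, seed = seed)
  structure(list(table = res, n_perm = n_perm, seed = seed,
                 terms = terms, n = n),
            class = "kelp_permanova")
}

# Core Freedman-Lane engine on a Gower-centered matrix G.
permanova_engine <- function(G, X, asgn, term_ids, term_labels, n_perm, seed) {
  n <- nrow(G)
  n_perm <- check_count(n_perm, "n_perm", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)

  hat_of <- function(Xs) {
    q <- qr(Xs)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  H_full <- hat_of(X)
  rank_full <- qr(X)$rank
  ss_total <- sum(diag(G))
  ss_res <- ss_total - sum(H_full * G)
  df_res <- n - rank_full
  ms_res <- ss_res / df_res

  rows <- vector("list", length(term_ids))
  with_seed(seed, {
    for (i in seq_along(term_ids)) {
      k <- term_ids[i]
      X_red <- X[, asgn != k, drop = FALSE]
      H_red <- hat_of(X_red)
      df_k <- rank_full - qr(X_red)$rank
      ss_k <- sum(H_full * G) - sum(H_red * G)
      F_k <- (ss_k / df_k) / ms_res

      # Freedman-Lane: permute reduced-model residuals of G
      R <- diag(n) - H_red
      E <- R %*% G %*% R
      Fit <- H_red %*% G %*% H_red
      count <- 0L
      for (b in seq_len(n_perm)) {
        p <- sample.int(n)
        Gp <- Fit + E[p, p]
        ss_kp <- sum(H_full * Gp) - sum(H_red * Gp)
        ss_rp <- sum(diag(Gp)) - sum(H_full * Gp)
        F_p <- (ss_kp / df_k) / (ss_rp / df_res)
        if (F_p >= F_k - 1e-12) count <- count + 1L
      }
      rows[[i]] <- tibble::tibble(
        term = term_labels[i], df = df_k, SS = ss_k, MS = ss_k / df_k,
        pseudo_F = F_k, p_perm = (count + 1L) / (n_perm + 1L)
      )
    }
  })

  dplyr::bind_rows(
    dplyr::bind_rows(rows),
    tibble::tibble(term = "Residual", df = df_res, SS = ss_res, MS = ms_res,
                   pseudo_F = NA_real_, p_perm = NA_real_),
    tibble::tibble(term = "Total", df = n - 1L, SS = ss_total, MS = NA_real_,
                   pseudo_F = NA_real_, p_perm = NA_real_)
  )
}

# One-way PERMANOVA (used by pairwise comparisons and calibration tests)
permanova_oneway <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as_distance_matrix(d)
  g <- factor(groups)
  if (nlevels(g) < 2L) abort("Need at least 2 groups.")
  X <- stats::model.matrix(~ g, contrasts.arg = list(g = "contr.sum"))
  asgn <- attr(X, "assign")
  permanova_engine(gower_center(d), X, asgn, term_ids = 1L,
                   term_labels = "group", n_perm = n_perm, seed = seed)
}

#' @export
print.kelp_permanova <- function(x, ...) {
  cat(sprintf("Two-way PERMANOVA (Type III, %d permutations of reduced-model residuals)\n",
              x$n_perm))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pairwise PERMANOVA comparisons within strata
#'
#' For each level of the stratifying factor, compares every pair of levels of
#' the tested factor with a one-way two-group PERMANOVA restricted to that
#' stratum, reporting `t = sqrt(pseudo-F)` and a permutation p-value. Level
#' pairs with fewer than 2 samples in a group are skipped with a warning.
#'
#' @inheritParams permanova_2way
#' @param test_factor Name of the factor whose levels are compared.
#' @param stratum Name of the stratifying factor, or `NULL` for none.
#' @return Tibble with `stratum`, `level_1`, `level_2`, `t`, `p_perm`, `n`.
#' @export
pairwise_permanova <- function(d, factors, test_factor, stratum = NULL,
                               n_perm = 999, seed = 1) {
  d <- as_distance_matrix(d)
  if ("sample_id" %in% names(factors) && !is.null(rownames(d))) {
    ord <- match(rownames(d), factors$sample_id)
    if (anyNA(ord)) abort("`factors$sample_id` does not cover the distance matrix.")
    factors <- factors[ord, ]
  }
  strata <- if (is.null(stratum)) list(all = seq_len(nrow(d))) else
    split(seq_len(nrow(d)), factors[[stratum]])

  out <- list()
  for (s in names(strata)) {
    idx <- strata[[s]]
    g <- factor(factors[[test_factor]][idx])
    levs <- levels(droplevels(g))
    if (length(levs) < 2L) next
    for (i in seq_len(length(levs) - 1L)) {
      for (j in (i + 1L):length(levs)) {
        sel <- idx[g %in% c(levs[i], levs[j])]
        gg <- droplevels(factor(factors[[test_factor]][sel]))
        if (min(table(gg)) < 2L) {
          warn(sprintf("Skipping %s vs %s in stratum '%s': a group has < 2 samples.",
                       levs[i], levs[j], s))
          next
        }
        tab <- permanova_oneway(d[sel, sel], gg, n_perm = n_perm, seed = seed)
        out[[length(out) + 1L]] <- tibble::tibble(
          stratum = if (is.null(stratum)) NA_character_ else s,
          level_1 = levs[i], level_2 = levs[j],
          t = sqrt(tab$pseudo_F[1]), p_perm = tab$p_perm[1],
          n = length(sel)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}
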