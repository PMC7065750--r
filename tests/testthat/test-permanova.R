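test_that("an 18-sample 2x2 design partitions the published degrees of freedom", {
  tabs <- sim_survey_tables(survey_spec(n_sites_per_cell = c(5, 5, 4, 4),
                                        seed = 1))
  d <- bray_curtis(ln1p_transform(tabs$abundance))
  pm <- permanova_2way(d, tabs$factors, n_perm = 19, seed = 1)
  expect_equal(pm$table$term,
               c("location", "exposure", "location:exposure", "Residual", "Total"))
  expect_equal(pm$table$df, c(1, 1, 1, 14, 17))
  expect_true(all(pm$table$p_perm[1:3] >= 1 / 20 &
                  pm$table$p_perm[1:3] <= 1))
  expect_equal(sum(pm$table$df[1:4]), pm$table$df[5])
})

test_that("pseudo-F agrees with the vegan reference on a balanced design", {
  skip_if_not_installed("vegan")
  tabs <- sim_survey_tables(survey_spec(n_sites_per_cell = 5, seed = 4))
  d <- bray_curtis(ln1p_transform(tabs$abundance))
  pm <- permanova_2way(d, tabs$factors, n_perm = 19, seed = 2)
  avm <- vegan::adonis2(stats::as.dist(d) ~ location * exposure,
                        data = as.data.frame(tabs$factors),
                        by = "margin", permutations = 19)
  # vegan's by="margin" tests each marginal term against the full model:
  # its interaction row is exactly the Type III interaction
  expect_equal(pm$table$pseudo_F[3], avm["location:exposure", "F"],
               tolerance = 1e-10)
  # in a balanced design the factors are orthogonal, so sequential sums of
  # squares coincide with the partial (Type III) ones
  avt <- vegan::adonis2(stats::as.dist(d) ~ location * exposure,
                        data = as.data.frame(tabs$factors),
                        by = "terms", permutations = 19)
  expect_equal(pm$table$SS[1], avt["location", "SumOfSqs"], tolerance = 1e-10)
  expect_equal(pm$table$SS[2], avt["exposure", "SumOfSqs"], tolerance = 1e-10)
  expect_equal(pm$table$pseudo_F[1], avt["location", "F"], tolerance = 1e-10)
})

test_that("Monte-Carlo p matches exhaustive enumeration on a 6-sample toy", {
  set.seed(11)
  m <- matrix(rpois(6 * 5, 8), 6, 5)
  rownames(m) <- paste0("s", 1:6)
  d <- bray_curtis(m)
  g <- factor(rep(c("a", "b"), each = 3))

  # oracle: raw pseudo-F over all 720 label permutations, computed from
  # group sums of squared dissimilarities (no hat matrices)
  Fobs <- oneway_pseudo_F(d, g)
  Fs <- vapply(permn_all(1:6), function(p) oneway_pseudo_F(d, g[p]), numeric(1))
  p_exact <- mean(Fs >= Fobs - 1e-12)

  tab <- kelpcanopy:::permanova_oneway(d, g, n_perm = 999, seed = 3)
  expect_equal(tab$pseudo_F[1], Fobs, tolerance = 1e-10)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 1000)
  expect_lt(abs(tab$p_perm[1] - p_exact), 2 * mc_se + 1e-3)
})

test_that("confounded designs raise an explicit error", {
  f <- tibble::tibble(
    sample_id = paste0("s", 1:8),
    location = rep(c("IE", "MP"), each = 4),
    exposure = rep(c("exposed", "sheltered"), each = 4)  # aliased with location
  )
  set.seed(2)
  d <- bray_curtis(matrix(rpois(8 * 4, 6), 8, 4,
                          dimnames = list(f$sample_id, letters[1:4])))
  expect_error(permanova_2way(d, f, n_perm = 9, seed = 1), "Confounded|inestimable")
})

test_that("stronger planted effects raise PERMANOVA rejection monotonically", {
  pow <- vapply(c(1, 2.5, 6), function(mult) {
    hits <- 0L
    for (i in 1:12) {
      eff <- tibble::tibble(taxon = c("barnacle_dom", "urchin_chilean"),
                            factor = "exposure", level = "exposed",
                            multiplier = mult)
      tabs <- sim_survey_tables(survey_spec(effect_sizes = eff, seed = 300 + i))
      d <- bray_curtis(ln1p_transform(tabs$abundance))
      pm <- permanova_2way(d, tabs$factors, n_perm = 99, seed = i)
      hits <- hits + (pm$table$p_perm[2] <= 0.05)
    }
    hits / 12
  }, numeric(1))
  expect_true(pow[3] >= pow[1])
  expect_gte(pow[3], 0.8)   # large effects are detected essentially always
})

test_that("pairwise comparisons report t = sqrt(pseudo-F) with valid p", {
  tabs <- sim_survey_tables(survey_spec(n_sites_per_cell = 5, seed = 6))
  d <- bray_curtis(ln1p_transform(tabs$abundance))
  pw <- pairwise_permanova(d, tabs$factors, test_factor = "location",
                           stratum = "exposure", n_perm = 99, seed = 2)
  expect_equal(nrow(pw), 2)
  for (k in seq_len(nrow(pw))) {
    idx <- tabs$factors$exposure == pw$stratum[k]
    tab1 <- kelpcanopy:::permanova_oneway(
      d[idx, idx], factor(tabs$factors$location[idx]), n_perm = 9, seed = 1
    )
    expect_equal(pw$t[k]^2, tab1$pseudo_F[1], tolerance = 1e-10)
  }
  expect_true(all(pw$p_perm >= 1 / 100 & pw$p_perm <= 1))
})

test_that("near-duplicate groups are null; separated groups saturate the minimum p", {
  set.seed(8)
  base <- matrix(rpois(4 * 6, 9), 4, 6)
  dup <- rbind(base, base + matrix(rbinom(24, 1, 0.1), 4, 6))
  rownames(dup) <- paste0("s", 1:8)
  g <- tibble::tibble(sample_id = rownames(dup),
                      grp = rep(c("x", "y"), each = 4))
  pw_null <- pairwise_permanova(bray_curtis(dup), g, test_factor = "grp",
                                n_perm = 199, seed = 3)
  expect_gt(pw_null$p_perm[1], 0.2)

  sep <- rbind(cbind(matrix(rpois(12, 40), 6, 2), matrix(0, 6, 2)),
               cbind(matrix(0, 6, 2), matrix(rpois(12, 40), 6, 2)))
  rownames(sep) <- paste0("s", 1:12)
  g2 <- tibble::tibble(sample_id = rownames(sep),
                       grp = rep(c("x", "y"), each = 6))
  pw_sep <- pairwise_permanova(bray_curtis(sep), g2, test_factor = "grp",
                               n_perm = 199, seed = 4)
  expect_equal(pw_sep$p_perm[1], 1 / 200)

  # a level with fewer than 2 samples is skipped with a warning
  g3 <- tibble::tibble(sample_id = rownames(sep),
                       grp = c(rep("x", 11), "y"))
  expect_warning(
    pw3 <- pairwise_permanova(bray_curtis(sep), g3, test_factor = "grp",
                              n_perm = 9, seed = 1),
    "fewer|< 2"
  )
  expect_equal(nrow(pw3), 0)
})
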