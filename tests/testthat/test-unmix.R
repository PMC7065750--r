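lib6 <- sim_endmember_library(6, 6, seed = 21)

test_that("pure endmember pixels unmix to the exact fractions", {
  w <- lib6$water[1, ]
  expect_equal(unmix_pixel(lib6$kelp, lib6$kelp, w),
               list(fraction = 1, rmse = 0))
  expect_equal(unmix_pixel(w, lib6$kelp, w), list(fraction = 0, rmse = 0))
})

test_that("closed-form fraction matches the grid-search oracle", {
  w <- lib6$water[2, ]
  r <- 0.37 * lib6$kelp + 0.63 * w
  got <- unmix_pixel(r, lib6$kelp, w)
  expect_equal(got$fraction, 0.37, tolerance = 1e-12)
  g <- grid_unmix(r, lib6$kelp, w, step = 1e-4)
  expect_lt(abs(got$fraction - g$fraction), 1e-4)
  expect_lte(got$rmse, g$rmse + 1e-15)

  # noisy pixel: closed form can never do worse than the grid
  set.seed(1)
  rn <- r + rnorm(6, sd = 0.01)
  gotn <- unmix_pixel(rn, lib6$kelp, w)
  gn <- grid_unmix(rn, lib6$kelp, w, step = 1e-4)
  expect_lte(gotn$rmse, gn$rmse + 1e-12)
})

test_that("out-of-range solutions are clipped to physical fractions", {
  w <- lib6$water[1, ]
  over <- 1.4 * lib6$kelp - 0.4 * w
  expect_equal(unmix_pixel(over, lib6$kelp, w)$fraction, 1)
  under <- -0.2 * lib6$kelp + 1.2 * w
  expect_equal(unmix_pixel(under, lib6$kelp, w)$fraction, 0)
})

test_that("degenerate unmixing inputs error", {
  expect_error(unmix_pixel(1:5, 1:6, 1:6), "bands")
  expect_error(unmix_pixel(lib6$kelp, lib6$kelp, lib6$kelp), "Degenerate")
})

test_that("scene unmixing equals the exhaustive (pixel, endmember) double loop", {
  sp <- scene_spec(n_rows = 8, n_cols = 8, noise_sd = 0.01, cloud_prob = 0.1,
                   seed = 31)
  st <- sim_scene_series(sp, lib6)
  m <- unmix_scene(st$scenes[[1]], lib6, st$cloud[[1]])
  o <- brute_unmix_scene(st$scenes[[1]], lib6, st$cloud[[1]])
  expect_equal(m$fraction, o$fraction, tolerance = 1e-12)
  expect_equal(m$rmse, o$rmse, tolerance = 1e-12)
  expect_identical(m$endmember, o$endmember)
})

test_that("chosen model is optimal: no endmember beats the reported rmse", {
  sp <- scene_spec(n_rows = 5, n_cols = 5, noise_sd = 0.02, seed = 7)
  st <- sim_scene_series(sp, lib6)
  m <- unmix_scene(st$scenes[[1]], lib6, st$cloud[[1]])
  for (p in which(m$valid)) {
    r <- matrix(st$scenes[[1]], 25, 6)[p, ]
    rmses <- apply(lib6$water, 1, function(w) {
      unmix_pixel(r, lib6$kelp, w)$rmse
    })
    expect_lte(m$rmse[p], min(rmses) + 1e-14)
  }
})

test_that("recovered fraction is strictly increasing in true fraction", {
  w <- lib6$water[3, ]
  fs <- seq(0, 1, by = 0.05)
  rec <- vapply(fs, function(f) {
    unmix_pixel(f * lib6$kelp + (1 - f) * w, lib6$kelp, w)$fraction
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("fraction error stays small under realistic sensor noise", {
  sp <- scene_spec(n_rows = 12, n_cols = 12, noise_sd = 0.01,
                   water_variability = 0, cloud_prob = 0, seed = 13)
  st <- sim_scene_series(sp, lib6)
  errs <- vapply(seq_along(st$dates), function(d) {
    m <- unmix_scene(st$scenes[[d]], lib6)
    mean(abs(m$fraction - st$truth[[d]]))
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
})

test_that("fully clouded scenes yield no valid pixels", {
  sp <- scene_spec(n_rows = 4, n_cols = 4, cloud_prob = 1, seed = 9)
  st <- sim_scene_series(sp, lib6)
  m <- unmix_scene(st$scenes[[1]], lib6, st$cloud[[1]])
  expect_equal(sum(m$valid), 0)
  expect_true(all(is.na(m$fraction)))
})

test_that("cloud filter removes dates strictly above the 25% threshold", {
  frac <- matrix(0.5, 10, 10)
  v26 <- matrix(TRUE, 10, 10); v26[seq_len(26)] <- FALSE   # 26% obscured
  v25 <- matrix(TRUE, 10, 10); v25[seq_len(25)] <- FALSE   # exactly 25%
  maps <- list(make_map(frac, v26), make_map(frac, v25),
               make_map(frac))                              # cloud-free
  out <- site_cloud_filter(maps, site_pixels = 1:100, threshold = 0.25)
  expect_equal(out$retained, c(FALSE, TRUE, TRUE))
  expect_equal(out$n_obscured, c(26L, 25L, 0L))
  expect_error(site_cloud_filter(maps, integer(0)), "non-empty")
})
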