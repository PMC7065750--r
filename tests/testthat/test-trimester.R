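test_that("observations in one trimester are averaged with their count", {
  obs <- tibble::tibble(
    date = as.Date(c("1998-02-01", "1998-03-15", "1998-06-01")),
    value = c(2, 4, 10)
  )
  ts <- to_trimesters(obs)
  expect_equal(ts$value[1], 3)
  expect_equal(ts$n_obs[1], 2L)
  expect_equal(ts$value[2], 10)
  expect_equal(ts$date, as.Date(c("1998-01-01", "1998-05-01")))
})

test_that("interior gaps are linearly interpolated and flagged", {
  obs <- tibble::tibble(
    date = as.Date(c("1998-02-01", "1998-10-01")),  # trimesters 1 and 3
    value = c(2, 6)
  )
  ts <- to_trimesters(obs)
  expect_equal(ts$value, c(2, 4, 6))
  expect_equal(ts$n_obs, c(1L, 0L, 1L))
})

test_that("trimester aggregation is idempotent on constants and spans years", {
  obs <- tibble::tibble(
    date = as.Date(c("1998-02-01", "1998-06-01", "1999-02-01", "1999-10-01")),
    value = rep(5, 4)
  )
  ts <- to_trimesters(obs)
  expect_equal(ts$value, rep(5, 6))
  expect_equal(nrow(ts), 6)        # trimester 1 1998 .. trimester 3 1999
  expect_equal(diff(ts$trimester), rep(1L, 5))
  expect_error(to_trimesters(obs[1, ]), "two dated")
})

test_that("proportional standardization maps onto [0, 1] and is scale invariant", {
  obs <- tibble::tibble(date = as.Date(c("1998-02-01", "1998-06-01", "1998-10-01")),
                        value = c(2.1, 8.4, 4.2))
  ts <- to_trimesters(obs)
  st <- proportional_standardize(ts)
  expect_equal(max(st$value), 1)
  expect_equal(st$value, c(0.25, 1, 0.5))

  ts17 <- ts; ts17$value <- ts$value * 17
  expect_equal(proportional_standardize(ts17)$value, st$value)

  zero <- ts; zero$value <- 0
  expect_equal(proportional_standardize(zero)$value, c(0, 0, 0))
})

test_that("regional series averages image sums within trimesters", {
  fr <- function(v) make_map(matrix(v, 2, 2))
  maps <- list(
    make_map(matrix(10 / 4, 2, 2), date = as.Date("1998-01-10")),
    make_map(matrix(20 / 4, 2, 2), date = as.Date("1998-02-10")),
    make_map(matrix(30 / 4, 2, 2), date = as.Date("1998-03-10")),
    make_map(matrix(40 / 4, 2, 2), date = as.Date("1998-06-10"))
  )
  rs <- regional_series(maps, standardize = FALSE)
  expect_equal(rs$value, c(20, 40))  # mean(10, 20, 30) then 40

  # two identical images in a trimester equal one
  rs2 <- regional_series(maps[c(1, 1, 4)], standardize = FALSE)
  expect_equal(rs2$value[1], 10)
})

test_that("running mean behaves at its limits", {
  const <- rep(3.5, 10)
  expect_equal(running_mean(const, 6), const)
  expect_equal(running_mean(c(1, 4, 2, 8), 1), c(1, 4, 2, 8))

  impulse <- c(0, 0, 6, 0, 0, 0)
  rm6 <- running_mean(impulse, 6)
  expect_true(any(abs(rm6 - 1) < 1e-12))  # full-window positions average to 1
  expect_equal(sum(is.na(rm6)), 0)

  # missing steps are excluded from each window
  with_na <- c(1, NA, 3)
  expect_equal(running_mean(with_na, 3), c(1, 2, 3))
})

test_that("running mean and trimester aggregation commute with adding a constant", {
  set.seed(14)
  obs <- tibble::tibble(
    date = sort(sample(seq(as.Date("1998-01-01"), as.Date("2002-12-01"), by = "day"), 25)),
    value = runif(25, 0, 5)
  )
  base <- running_mean(to_trimesters(obs), 6)$value
  shifted <- obs; shifted$value <- obs$value + 11
  expect_equal(running_mean(to_trimesters(shifted), 6)$value, base + 11)
})
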