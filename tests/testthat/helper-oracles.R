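# Independent oracles used across tests; deliberately written as plain,
# scalar-level code so they share no path with the package implementation.

# all permutations of a vector (used for exhaustive permutation p-values)
permn_all <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in permn_all(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# grid-search unmixing oracle: best f over a fine grid
grid_unmix <- function(r, kelp, water, step = 1e-4) {
  fs <- seq(0, 1, by = step)
  rmse <- vapply(fs, function(f) {
    sqrt(mean((r - (f * kelp + (1 - f) * water))^2))
  }, numeric(1))
  i <- which.min(rmse)
  list(fraction = fs[i], rmse = rmse[i])
}

# exhaustive double loop over (pixel, endmember) pairs for a whole scene
brute_unmix_scene <- function(scene, library, cloud_mask = NULL) {
  nr <- dim(scene)[1]; nc <- dim(scene)[2]
  if (is.null(cloud_mask)) cloud_mask <- matrix(FALSE, nr, nc)
  fr <- matrix(NA_real_, nr, nc)
  rm <- matrix(NA_real_, nr, nc)
  em <- matrix(NA_integer_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (cloud_mask[i, j]) next
      r <- scene[i, j, ]
      best <- Inf
      for (k in seq_len(nrow(library$water))) {
        w <- library$water[k, ]
        d <- library$kelp - w
        f <- sum((r - w) * d) / sum(d * d)
        f <- min(1, max(0, f))
        rmse <- sqrt(mean((r - (f * library$kelp + (1 - f) * w))^2))
        if (rmse < best) {
          best <- rmse
          fr[i, j] <- f; rm[i, j] <- rmse; em[i, j] <- k
        }
      }
    }
  }
  list(fraction = fr, rmse = rm, endmember = em)
}

# one-way pseudo-F computed from first principles (hat-matrix free):
# among/within group sums of squared dissimilarities (Anderson 2001)
oneway_pseudo_F <- function(d, groups) {
  g <- factor(groups)
  n <- length(g)
  a <- nlevels(g)
  SST <- sum(d[upper.tri(d)]^2) / n
  SSW <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    sub <- d[idx, idx, drop = FALSE]
    SSW <- SSW + sum(sub[upper.tri(sub)]^2) / length(idx)
  }
  SSA <- SST - SSW
  (SSA / (a - 1)) / (SSW / (n - a))
}

# tiny fraction-map builder for cloud-filter and extraction tests
make_map <- function(fraction, valid = NULL, date = as.Date("2000-02-01")) {
  fraction <- as.matrix(fraction)
  if (is.null(valid)) valid <- !is.na(fraction)
  fr <- fraction
  fr[!valid] <- NA_real_
  structure(
    list(fraction = fr, rmse = matrix(0, nrow(fr), ncol(fr)),
         endmember = NULL, valid = valid, date = date),
    class = "fraction_map"
  )
}
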