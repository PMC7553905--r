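lf_small <- function() toy_leadfield(32, 60, seed = 14)

test_that("inverse estimates are invariant to common offsets and vanish as lambda grows", {
  lf <- lf_small()
  inv <- build_inverse_operator(lf)
  set.seed(1)
  x <- matrix(rnorm(32 * 4), 32)
  est1 <- apply_inverse(inv, x)
  est2 <- apply_inverse(inv, x + 7)
  expect_equal(est1$magnitude, est2$magnitude, tolerance = 1e-9)
  big <- build_inverse_operator(lf, lambda = 1e9)
  expect_lt(max(apply_inverse(big, x)$magnitude), 1e-6)
  expect_error(build_inverse_operator(lf, lambda = -1), "nonnegative")
})

test_that("a planted source is recovered at or next to its true point", {
  lf <- lf_small()
  inv <- build_inverse_operator(lf, lambda = 1e-8)
  for (pt in c(3, 25, 50)) {
    m <- c(0.5, -0.3, 0.8)
    topo <- lf$gain[, (3 * (pt - 1) + 1):(3 * pt)] %*% m
    est <- apply_inverse(inv, matrix(topo, ncol = 1))
    peak <- which.max(est$magnitude[, 1])
    d <- sqrt(colSums((t(lf$source_positions) - lf$source_positions[pt, ])^2))
    expect_lte(which(order(d) == peak), 4L)   # true point or 3 nearest
  }
})

test_that("doubling the data does not change standardized source maps", {
  lf <- lf_small()
  inv <- build_inverse_operator(lf)
  set.seed(2)
  x <- matrix(rnorm(32 * 50), 32)
  s1 <- standardize_sources(apply_inverse(inv, x))
  s2 <- standardize_sources(apply_inverse(inv, 2 * x))
  expect_equal(s1$magnitude, s2$magnitude, tolerance = 1e-9)
  sds <- apply(s1$magnitude[!s1$degenerate, , drop = FALSE], 1, sd)
  expect_equal(sds, rep(1, length(sds)), tolerance = 1e-9)
})

test_that("constant time courses standardize to flagged zeros", {
  est <- structure(list(magnitude = rbind(c(1, 1, 1), c(1, 2, 3)),
                        moments = NULL, source_positions = diag(3)[1:2, ]),
                   class = "source_estimate")
  out <- standardize_sources(est)
  expect_true(out$degenerate[1])
  expect_equal(out$magnitude[1, ], c(0, 0, 0))
})

test_that("per-microstate source maps average the labelled time points", {
  lf <- lf_small()
  inv <- build_inverse_operator(lf)
  set.seed(3)
  x <- matrix(rnorm(32 * 40), 32)
  est <- standardize_sources(apply_inverse(inv, x))
  lab <- rep(1L, 40)
  expect_equal(microstate_source_map(est, lab, 1), rowMeans(est$magnitude),
               tolerance = 1e-12)
  expect_true(all(is.na(microstate_source_map(est, lab, 2))))
  # joint time permutation changes nothing
  perm <- sample(40)
  est_p <- est; est_p$magnitude <- est$magnitude[, perm]
  expect_equal(microstate_source_map(est_p, lab[perm], 1),
               microstate_source_map(est, lab, 1), tolerance = 1e-12)
})

test_that("percentile mask keeps strictly-above points, empty under ties", {
  set.seed(4)
  v <- sample(seq_len(100))
  mask <- percentile_threshold(v, 95)
  expect_equal(sum(mask), 5L)
  expect_equal(sort(v[mask]), 96:100)
  # sort-based oracle on arbitrary values
  w <- rnorm(137)
  mask2 <- percentile_threshold(w, 95)
  thr <- sort(w)[ceiling(0.95 * (137 - 1)) + 1]   # type-7 quantile at p=.95
  expect_equal(which(mask2), which(w > quantile(w, 0.95, names = FALSE)))
  expect_equal(sum(percentile_threshold(rep(3, 50), 95)), 0L)
})

test_that("voxelwise randomization flags planted differences only", {
  n_sub <- 12; n_pts <- 40
  set.seed(6)
  base <- matrix(rnorm(n_sub * n_pts), n_sub)
  maps_a <- base
  maps_b <- base
  maps_a[, 11] <- maps_a[, 11] + 1          # planted difference
  mask <- rep(FALSE, n_pts); mask[6:15] <- TRUE
  res <- voxelwise_randomization(maps_a, maps_b, mask, alpha = 0.005)
  expect_true(res$significant[res$point == 11])
  expect_false(any(res$significant[res$point != 11]))
  # identical maps: nothing significant
  res0 <- voxelwise_randomization(maps_a, maps_a, mask, alpha = 0.005)
  expect_false(any(res0$significant))
  # alpha = 1 marks every retained point (generic paired noise)
  maps_c <- base + matrix(rnorm(n_sub * n_pts, sd = 0.1), n_sub)
  res1 <- voxelwise_randomization(maps_a, maps_c, mask, alpha = 1)
  expect_true(all(res1$significant))
})
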