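test_that("pairwise dissimilarity is polarity-invariant with the right limits", {
  a <- rnorm(8)
  D <- pairwise_dissimilarity(cbind(a, a, -a))
  expect_equal(max(abs(D)), 0, tolerance = 1e-12)
  # orthogonal (after centring) maps sit at sqrt(2)
  m <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1))
  expect_equal(pairwise_dissimilarity(m)[1, 2], sqrt(2), tolerance = 1e-12)
  expect_error(pairwise_dissimilarity(cbind(a, rep(1, 8))),
               class = "sleepstates_zero_variance")
})

test_that("all seven criteria match brute-force oracles on random instances", {
  set.seed(77)
  for (rep in 1:3) {
    ts <- make_templates(8, 4, seed = rep * 7)
    pm <- fix_peak_maps(ts, n = 30, seed = rep * 13, noise_sd = 0.25)
    fits <- lapply(2:4, function(k) {
      modified_kmeans(pm$maps, k, kmeans_config(n_restarts = 5, seed = rep))
    })
    names(fits) <- 2:4
    prof <- compute_validity_criteria(pm$maps, fits)
    X <- sweep(pm$maps, 2, colMeans(pm$maps), "-")
    D <- oracle_dissim(X)
    Ws <- numeric(3)
    for (i in 1:3) {
      lab <- fits[[i]]$labels
      tmpl <- fits[[i]]$templates$maps
      expect_equal(prof$gamma[i], oracle_gamma(D, lab), tolerance = 1e-8)
      expect_equal(prof$silhouette[i], oracle_silhouette(D, lab),
                   tolerance = 1e-8)
      expect_equal(prof$davies_bouldin[i], oracle_db(X, tmpl, lab),
                   tolerance = 1e-8)
      expect_equal(prof$point_biserial[i], oracle_pb(D, lab),
                   tolerance = 1e-8)
      expect_equal(prof$dunn[i], oracle_dunn(D, lab), tolerance = 1e-8)
      expect_equal(prof$cross_validation[i],
                   oracle_cv(X, tmpl, lab), tolerance = 1e-8)
      Ws[i] <- oracle_W(X, tmpl, lab)
    }
    p <- nrow(X)
    diff_k <- function(k, Wm1, Wk) (k - 1)^(2 / p) * Wm1 - k^(2 / p) * Wk
    kl3 <- abs(diff_k(3, Ws[1], Ws[2])) / abs(diff_k(4, Ws[2], Ws[3]))
    expect_equal(prof$krzanowski_lai[2], kl3, tolerance = 1e-8)
    expect_true(all(is.na(prof$krzanowski_lai[c(1, 3)])))
  }
})

test_that("ideal separation drives the criteria to their limits", {
  # two tight, well-separated clusters in map space
  ts <- make_templates(12, 2, seed = 5, template_min_separation = 0.1)
  pm <- fix_peak_maps(ts, n = 24, seed = 6, noise_sd = 0.01)
  fit <- modified_kmeans(pm$maps, 2, kmeans_config(n_restarts = 5, seed = 1))
  prof <- compute_validity_criteria(pm$maps, list(`2` = fit))
  expect_gt(prof$silhouette, 0.9)
  expect_lt(prof$davies_bouldin, 0.2)
  expect_equal(prof$gamma, 1, tolerance = 1e-12)
})

test_that("criteria are invariant to sign flips and cluster relabelling", {
  ts <- make_templates(8, 3, seed = 9)
  pm <- fix_peak_maps(ts, n = 24, seed = 10, noise_sd = 0.2)
  fit <- modified_kmeans(pm$maps, 3, kmeans_config(n_restarts = 5, seed = 1))
  prof1 <- compute_validity_criteria(pm$maps, list(`3` = fit))
  flip <- fit
  perm <- c(2L, 3L, 1L)
  flip$labels <- perm[fit$labels]
  flip$templates <- template_set(fit$templates$maps[, order(perm)] *
                                   rep(c(-1, 1, -1), each = 8))
  set.seed(11)
  maps_flipped <- sweep(pm$maps, 2, sample(c(-1, 1), 24, TRUE), "*")
  prof2 <- compute_validity_criteria(maps_flipped, list(`3` = flip))
  for (crit in c("gamma", "silhouette", "davies_bouldin", "point_biserial",
                 "dunn", "cross_validation")) {
    expect_equal(prof1[[crit]], prof2[[crit]], tolerance = 1e-10)
  }
})

test_that("per-criterion optima follow the max/min direction with small-K ties", {
  prof <- data.frame(K = 2:6,
                     gamma = c(0.2, 0.9, 0.9, 0.5, 0.1),
                     silhouette = c(0.1, 0.2, 0.8, 0.2, 0.1),
                     davies_bouldin = c(3, 2, 0.5, 2, 3),
                     point_biserial = c(0.3, 0.3, 0.3, 0.3, 0.3),
                     dunn = c(0.1, 0.4, 2, 0.5, 0.2),
                     krzanowski_lai = c(NA, 1, 9, 1, NA),
                     cross_validation = c(5, 4, 1, 2, 3))
  opt <- select_optimal_k(prof)
  expect_equal(unname(opt[c("silhouette", "davies_bouldin", "dunn",
                            "krzanowski_lai", "cross_validation")]),
               rep(4L, 5))
  expect_equal(unname(opt["gamma"]), 3L)         # tie toward smaller K
  expect_equal(unname(opt["point_biserial"]), 2L) # flat: smallest tested K
})

test_that("meta-criterion takes the median with the lower-middle even rule", {
  expect_equal(meta_criterion(rep(5, 7)), 5L)
  expect_equal(meta_criterion(c(4, 4, 5, 5, 5, 6, 7)), 5L)
  expect_equal(meta_criterion(c(4, 5, 6, 7)), 5L)
  expect_error(meta_criterion(integer(0)), "empty")
})
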