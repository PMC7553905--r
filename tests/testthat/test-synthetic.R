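test_that("planted templates are average-referenced, unit-norm, separated and deterministic", {
  ts <- make_templates(64, 5, seed = 1, template_min_separation = 0.5)
  expect_equal(dim(ts$maps), c(64L, 5L))
  expect_lt(max(abs(colSums(ts$maps))), 1e-12)
  expect_equal(unname(colSums(ts$maps^2)), rep(1, 5), tolerance = 1e-12)
  # exhaustive pair check of the separation bound
  worst <- 0
  for (i in 1:4) for (j in (i + 1):5) {
    worst <- max(worst, abs(oracle_pearson(ts$maps[, i], ts$maps[, j])))
  }
  expect_lte(worst, 0.5)
  ts2 <- make_templates(64, 5, seed = 1, template_min_separation = 0.5)
  expect_identical(ts$maps, ts2$maps)
  expect_error(make_templates(32, 5, seed = 1,
                              template_min_separation = 0.01,
                              max_attempts = 50),
               "could not find")
})

test_that("noiseless recordings correlate perfectly with their generating template", {
  sim <- fix_recording(snr = Inf, epoch_length = 2, n_epochs = 1)
  X <- sim$recording$data
  for (t in seq(1, ncol(X), by = 7)) {
    expect_equal(abs(oracle_pearson(X[, t],
                                    sim$truth$templates$maps[, sim$truth$labels[t]])),
                 1, tolerance = 1e-9)
  }
})

test_that("empirical segment durations match the configured mean", {
  ts <- fix_templates(16, 3)
  cfg <- generator_config(n_channels = 16, n_maps = 3, epoch_length = 30,
                          n_epochs = 2, mean_duration = 80, seed = 5)
  sim <- simulate_recording(cfg, ts)
  seg <- sim$truth$segments
  mean_ms <- mean(seg$end - seg$start) * 1000 / cfg$sfreq
  expect_lt(abs(mean_ms - 80) / 80, 0.10)
})

test_that("coverage constraints are honoured", {
  ts <- fix_templates(16, 3)
  cfg <- generator_config(n_channels = 16, n_maps = 3, epoch_length = 5,
                          n_epochs = 1, seed = 2)
  sim <- simulate_recording(cfg, ts, condition_coverage = c(1, 0, 0))
  expect_true(all(sim$truth$labels == 1L))
  expect_error(simulate_recording(cfg, ts, condition_coverage = c(0.6, 0.3, 0.3)),
               "sum to 1")
  # long-run coverage approaches the requested stationary distribution
  cfg2 <- generator_config(n_channels = 16, n_maps = 3, epoch_length = 60,
                           n_epochs = 2, seed = 3, mean_duration = 60)
  target <- c(0.5, 0.3, 0.2)
  sim2 <- simulate_recording(cfg2, ts, condition_coverage = target)
  emp <- tabulate(sim2$truth$labels, 3) / length(sim2$truth$labels)
  expect_lt(max(abs(emp - target)), 0.06)
})

test_that("recordings are bit-identical under identical seeds", {
  a <- fix_recording(seed = 7)
  b <- fix_recording(seed = 7)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$labels, b$truth$labels)
})

test_that("polarity flips change only segment signs, not correlation structure", {
  ts <- fix_templates(16, 3)
  mk <- function(p) {
    cfg <- generator_config(n_channels = 16, n_maps = 3, epoch_length = 3,
                            n_epochs = 1, snr = Inf, polarity_flip_prob = p,
                            seed = 9)
    simulate_recording(cfg, ts)
  }
  a <- mk(0); b <- mk(1)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_equal(a$recording$data, -b$recording$data, tolerance = 1e-12)
  expect_true(all(a$truth$signs == 1) && all(b$truth$signs == -1))
})

test_that("carrier spectra concentrate in the planted band", {
  ts <- fix_templates(16, 2)
  cfg <- generator_config(n_channels = 16, n_maps = 2, epoch_length = 20,
                          n_epochs = 1, snr = Inf, seed = 13,
                          mean_duration = 2000,
                          carrier_bands = rbind(c(8.5, 12), c(1, 4)))
  sim <- simulate_recording(cfg, ts)
  # amplitude time course on the best channel of map 1, map-1 samples only
  ch <- which.max(abs(ts$maps[, 1]))
  idx <- which(sim$truth$labels == 1L)
  frac <- fft_band_fraction(sim$recording$data[ch, idx], cfg$sfreq,
                            c(8, 12.5))
  expect_gt(frac, 0.6)
})

test_that("group simulation plants exact coverage shifts and jitter", {
  des <- group_design(n_subjects = 3, delta = 0.10, jitter_corr = 0.9, K = 4,
                      effect_maps = c(3, 4))
  expect_equal(des$coverage[1, ] - des$coverage[2, ], c(0, 0, 0.10, -0.10))
  expect_error(group_design(delta = 0.9, K = 4), "outside")
  d0 <- group_design(n_subjects = 2, delta = 0, K = 4)
  expect_equal(d0$coverage[1, ], d0$coverage[2, ])
  cfg <- generator_config(n_channels = 16, n_maps = 4, epoch_length = 2,
                          n_epochs = 1, sfreq = 100, seed = 4)
  g <- simulate_group(des, cfg)
  cors <- unlist(lapply(g$subjects, function(s) {
    vapply(1:4, function(k) {
      abs(oracle_pearson(s$templates$maps[, k], g$group_templates$maps[, k]))
    }, numeric(1))
  }))
  expect_true(all(abs(cors - 0.9) < 1e-9))
  expect_gte(mean(cors), 0.85)
  expect_lte(mean(cors), 0.95)
})

test_that("toy lead field is average-referenced, depth-sensitive and flags centre sources", {
  lf <- toy_leadfield(32, 20, seed = 6)
  expect_lt(max(abs(colSums(lf$gain))), 1e-9)
  expect_true(all(is.finite(lf$gain)))
  # superficial source beats the same-moment deep source in gain norm
  lf2 <- toy_leadfield(32, source_positions = rbind(c(0, 0, 0.8),
                                                    c(0, 0, 0.2)))
  expect_gt(sqrt(sum(lf2$gain[, 1:3]^2)), sqrt(sum(lf2$gain[, 4:6]^2)))
  # centre source: zero columns + degenerate flag
  lf3 <- toy_leadfield(32, source_positions = rbind(c(0, 0, 0), c(0, 0, 0.5)))
  expect_true(lf3$degenerate[1])
  expect_false(lf3$degenerate[2])
  expect_equal(max(abs(lf3$gain[, 1:3])), 0)
  expect_error(toy_leadfield(32, source_positions = rbind(c(0, 0, 1))),
               "outside")
})
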