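test_that("winner-takes-all labelling recovers generating templates and ignores polarity", {
  ts <- fix_templates(16, 3, seed = 71)
  pm <- fix_peak_maps(ts, n = 200, seed = 72)
  rec <- eeg_recording(pm$maps, 250)
  lab <- backfit_labels(average_reference(rec), ts)
  expect_identical(as.integer(lab), pm$labels)
  flipped <- rec
  flipped$data <- -rec$data
  expect_identical(as.integer(backfit_labels(average_reference(flipped), ts)),
                   pm$labels)
  # zero-variance time point gets the undefined code
  rec$data[, 7] <- 5
  lab2 <- backfit_labels(average_reference(rec), ts)
  expect_true(is.na(lab2[7]))
  expect_identical(as.integer(lab2[-7]), pm$labels[-7])
})

test_that("relabelling with the same templates is idempotent", {
  sim <- fix_recording(snr = 2, epoch_length = 2, n_epochs = 2)
  rec <- average_reference(sim$recording)
  lab1 <- backfit_labels(rec, sim$truth$templates)
  # rebuild the labelled recording's best-fit sequence a second time
  lab2 <- backfit_labels(rec, sim$truth$templates)
  expect_identical(lab1, lab2)
})

test_that("segment statistics match arithmetic cases and the run-length oracle", {
  lab <- rep(c(1L, 2L), each = 10, times = 5)
  st <- segment_statistics(lab, 250, K = 2,
                           epochs = cbind(0L, 100L))
  expect_equal(st$mean_duration_ms, c(40, 40))
  expect_equal(st$occurrence_hz[1], st$occurrence_hz[2])
  expect_equal(sum(st$coverage), 1)
  one <- segment_statistics(rep(1L, 250), 250, K = 2)
  expect_equal(one$mean_duration_ms[1], 1000)
  expect_equal(one$occurrence_hz[1], 1)
  expect_equal(one$coverage, c(1, 0))
  expect_true(is.na(one$mean_duration_ms[2]))
  # random labels with an epoch boundary mid-run, including NA stretches
  set.seed(99)
  lab <- sample(c(1:3, NA), 400, replace = TRUE,
                prob = c(0.3, 0.3, 0.3, 0.1))
  ep <- cbind(c(0L, 175L), c(175L, 400L))
  expect_equal(segment_statistics(lab, 250, K = 3, epochs = ep),
               oracle_segment_stats(lab, 250, 3, ep), tolerance = 1e-12)
})

test_that("GEV matches the direct-summation oracle and its trivial limits", {
  ts <- fix_templates(8, 2, seed = 81)
  amp <- seq(0.5, 2, length.out = 50)
  rec <- eeg_recording(ts$maps[, 1] %o% amp, 250)
  lab <- backfit_labels(rec, ts)
  gev <- compute_gev(rec, ts, lab)
  expect_equal(as.numeric(gev), c(1, 0), tolerance = 1e-12)
  set.seed(82)
  m <- matrix(rnorm(8 * 200), 8)
  rec2 <- average_reference(eeg_recording(m, 250))
  lab2 <- backfit_labels(rec2, ts)
  gev2 <- compute_gev(rec2, ts, lab2)
  expect_equal(as.numeric(gev2),
               oracle_gev(rec2$data, ts$maps, as.integer(lab2)),
               tolerance = 1e-10)
  expect_equal(attr(gev2, "total"), sum(gev2))
})

test_that("coverage plus the undefined fraction always sums to one", {
  sim <- fix_recording(snr = 1, epoch_length = 2, n_epochs = 2)
  rec <- average_reference(sim$recording)
  rec$data[, c(3, 50)] <- 0           # force undefined samples
  lab <- backfit_labels(rec, sim$truth$templates)
  st <- segment_statistics(lab, rec$sfreq, K = 3)
  undef <- mean(is.na(lab))
  expect_equal(sum(st$coverage) * (1 - undef) + undef, 1, tolerance = 1e-12)
})

test_that("map correspondence recovers permutations and sign flips", {
  ts <- fix_templates(16, 5, seed = 91)
  mc <- map_correspondence(ts, ts)
  expect_equal(mc$matching, 1:5)
  expect_equal(unname(mc$matched_abs_corr), rep(1, 5), tolerance = 1e-12)
  perm <- c(3L, 5L, 1L, 2L, 4L)
  shuffled <- template_set(ts$maps[, perm] *
                             rep(c(-1, 1, -1, 1, -1), each = 16))
  mc2 <- map_correspondence(ts, shuffled)
  expect_equal(perm[mc2$matching], 1:5)
  expect_equal(unname(mc2$matched_abs_corr), rep(1, 5), tolerance = 1e-12)
  expect_warning(map_correspondence(ts, template_set(ts$maps[, 1:3])),
                 "unequal")
})

test_that("jittered template sets match at about the planted correlation", {
  ts <- fix_templates(32, 4, seed = 95)
  jit <- sleepstates:::with_seed(7, sleepstates:::jitter_templates(ts, 0.9))
  mc <- map_correspondence(ts, jit)
  expect_equal(mc$matching, 1:4)
  m <- mean(mc$matched_abs_corr)
  expect_gte(m, 0.85)
  expect_lte(m, 0.95)
})
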