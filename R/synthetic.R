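#' Configuration for the synthetic EEG generator
#'
#' Collects everything [simulate_recording()] needs to emit multichannel EEG
#' with planted microstate structure: piecewise-constant topographies of
#' sub-second duration riding on band-limited carriers, with polarity
#' inversions and additive sensor noise.
#'
#' @param n_channels number of electrodes.
#' @param sfreq sampling rate, Hz; must exceed twice the highest carrier
#'   frequency.
#' @param n_maps number of planted microstate maps K (>= 2).
#' @param epoch_length epoch length, seconds.
#' @param n_epochs number of independent epochs.
#' @param mean_duration mean microstate segment length, ms (sub-second
#'   microstate phenomenology is around 50-100 ms).
#' @param duration_shape gamma shape of the segment-duration distribution
#'   (mean fixed by `mean_duration`; durations truncated below at 2
#'   samples).
#' @param carrier_bands K x 2 matrix of per-map carrier bands `[f_lo, f_hi]`
#'   in Hz.  Default alternates delta (1-4 Hz) and alpha (8.5-12 Hz)
#'   carriers across maps, so slow- and fast-carrier states coexist as they
#'   do across sleep and wake.
#' @param carrier_mode `"noise"` (band-pass-filtered white noise; realistic
#'   spectra) or `"tone"` (pure sinusoid at the band centre; analytic
#'   tests).
#' @param snr linear amplitude ratio RMS(signal)/RMS(noise) over the whole
#'   recording; `Inf` disables noise.
#' @param polarity_flip_prob probability that a segment's topography is
#'   emitted with inverted sign.
#' @param seed integer RNG seed.
#' @param template_min_separation upper bound on pairwise absolute spatial
#'   correlation among planted maps, in (0, 1).
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_channels = 64L, sfreq = 250, n_maps = 5L,
                             epoch_length = 30, n_epochs = 2L,
                             mean_duration = 80, duration_shape = 2,
                             carrier_bands = NULL,
                             carrier_mode = c("noise", "tone"),
                             snr = 2, polarity_flip_prob = 0.5, seed = 1L,
                             template_min_separation = 0.5) {
  carrier_mode <- match.arg(carrier_mode)
  if (!is_count(n_maps) || n_maps < 2L) stopf("need n_maps >= 2")
  if (is.null(carrier_bands)) {
    carrier_bands <- matrix(rep_len(c(1, 4, 8.5, 12), 2L * n_maps),
                            ncol = 2L, byrow = TRUE)
  }
  carrier_bands <- matrix(as.numeric(carrier_bands), ncol = 2L)
  if (nrow(carrier_bands) != n_maps) stopf("need one carrier band per map")
  if (sfreq <= 2 * max(carrier_bands)) {
    stopf("sfreq must exceed twice the highest carrier frequency")
  }
  if (polarity_flip_prob < 0 || polarity_flip_prob > 1) {
    stopf("polarity_flip_prob must be in [0, 1]")
  }
  if (template_min_separation <= 0 || template_min_separation >= 1) {
    stopf("template_min_separation must be in (0, 1)")
  }
  structure(list(
    n_channels = as.integer(n_channels), sfreq = sfreq,
    n_maps = as.integer(n_maps), epoch_length = epoch_length,
    n_epochs = as.integer(n_epochs), mean_duration = mean_duration,
    duration_shape = duration_shape, carrier_bands = carrier_bands,
    carrier_mode = carrier_mode, snr = snr,
    polarity_flip_prob = polarity_flip_prob, seed = as.integer(seed),
    template_min_separation = template_min_separation),
    class = "generator_config")
}

#' Draw well-separated planted template maps
#'
#' Rejection-samples random average-referenced, unit-norm topographies until
#' K maps with pairwise absolute spatial correlation at most
#' `template_min_separation` are found.  Deterministic given `seed`.
#'
#' @param n_channels number of electrodes (> K).
#' @param K number of maps.
#' @param seed RNG seed.
#' @param template_min_separation bound on pairwise |spatial correlation|.
#' @param max_attempts rejection-sampling budget.
#' @return a [template_set()] of K maps.
#' @export
make_templates <- function(n_channels, K, seed,
                           template_min_separation = 0.5,
                           max_attempts = 5000L) {
  if (K >= n_channels) stopf("need K < n_channels")
  with_seed(seed, {
    maps <- matrix(0, n_channels, 0L)
    attempts <- 0L
    while (ncol(maps) < K) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stopf("could not find %d maps with |corr| <= %g in %d attempts",
              K, template_min_separation, max_attempts)
      }
      cand <- unitize_cols(matrix(stats::rnorm(n_channels), ncol = 1L))
      if (ncol(maps) == 0L ||
          max(abs(crossprod(maps, cand))) <= template_min_separation) {
        maps <- cbind(maps, cand)
      }
    }
    colnames(maps) <- paste0("map", seq_len(K))
    template_set(maps, provenance = "planted")
  })
}

# Jump chain with uniform off-diagonal structure over the active states and
# the per-state mean durations that make the long-run time coverage equal
# `coverage` exactly (see vignette): Q_ij = pi_j / (1 - pi_i) for i != j,
# with stationary distribution nu, and d_i = mean_dur * pi_i / nu_i.
segment_process <- function(coverage, mean_duration) {
  active <- which(coverage > 0)
  pi_a <- coverage[active] / sum(coverage[active])
  k <- length(active)
  if (k == 1L) {
    return(list(active = active, Q = matrix(1, 1, 1), start = 1,
                mean_dur = mean_duration))
  }
  Q <- outer(1 - pi_a, pi_a, function(d, p) p / d)
  diag(Q) <- 0
  Q <- Q / rowSums(Q)
  ev <- eigen(t(Q))
  i1 <- which.min(abs(ev$values - 1))
  nu <- abs(Re(ev$vectors[, i1]))
  nu <- nu / sum(nu)
  list(active = active, Q = Q, start = pi_a,
       mean_dur = mean_duration * pi_a / nu)
}

draw_epoch_labels <- function(n_samples, proc, shape, sfreq) {
  labels <- integer(n_samples)
  seg_start <- integer(0); seg_end <- integer(0); seg_state <- integer(0)
  pos <- 0L
  state <- sample.int(length(proc$start), 1L, prob = proc$start)
  while (pos < n_samples) {
    dur_ms <- stats::rgamma(1L, shape = shape,
                            scale = proc$mean_dur[state] / shape)
    len <- max(2L, as.integer(round(dur_ms / 1000 * sfreq)))
    len <- min(len, n_samples - pos)
    labels[(pos + 1L):(pos + len)] <- proc$active[state]
    seg_start <- c(seg_start, pos); seg_end <- c(seg_end, pos + len)
    seg_state <- c(seg_state, proc$active[state])
    pos <- pos + len
    if (length(proc$start) > 1L) {
      state <- sample.int(length(proc$start), 1L, prob = proc$Q[state, ])
    }
  }
  list(labels = labels,
       segments = data.frame(start = seg_start, end = seg_end,
                             map = seg_state))
}

band_carrier <- function(n, band, sfreq, mode) {
  if (mode == "tone") {
    f <- mean(band)
    ph <- stats::runif(1L, 0, 2 * pi)
    x <- sin(2 * pi * f * (seq_len(n) - 1L) / sfreq + ph)
  } else {
    bf <- signal::butter(4L, band / (sfreq / 2), type = "pass")
    x <- signal::filtfilt(bf, stats::rnorm(n))
  }
  x / sqrt(mean(x^2))
}

#' Simulate one recording with planted microstate ground truth
#'
#' Emits a concatenation of independent epochs.  Within each epoch a
#' semi-Markov state sequence (gamma-distributed segment durations, jump
#' chain tuned so long-run coverage matches `condition_coverage`) selects
#' which planted map is active; the data at time t equal that map's
#' topography times its band-limited carrier amplitude times a per-segment
#' random sign, plus spatially white sensor noise scaled to the requested
#' SNR.
#'
#' @param config a [generator_config()].
#' @param templates a [template_set()] with `config$n_maps` maps (defaults
#'   to [make_templates()] under the config's seed).
#' @param condition_coverage length-K nonnegative vector summing to 1; the
#'   planted long-run fraction of time in each state.  Default uniform.
#' @return list with elements `recording` (an [eeg_recording()]) and
#'   `truth` (planted templates, per-sample labels, segment table, planted
#'   coverage, carrier bands, per-segment signs).
#' @export
simulate_recording <- function(config, templates = NULL,
                               condition_coverage = NULL) {
  stopifnot(inherits(config, "generator_config"))
  K <- config$n_maps
  if (is.null(templates)) {
    templates <- make_templates(config$n_channels, K, config$seed,
                                config$template_min_separation)
  }
  if (ncol(templates$maps) != K) stopf("need %d templates", K)
  if (is.null(condition_coverage)) condition_coverage <- rep(1 / K, K)
  if (length(condition_coverage) != K) stopf("coverage vector must have length K")
  if (any(condition_coverage < 0) ||
      abs(sum(condition_coverage) - 1) > 1e-8) {
    stopf("coverage must be nonnegative and sum to 1")
  }
  n_ep <- config$n_epochs
  ep_len <- as.integer(round(config$epoch_length * config$sfreq))
  proc <- segment_process(condition_coverage, config$mean_duration)
  with_seed(config$seed, {
    lab_all <- integer(0)
    seg_all <- NULL
    sgn_all <- numeric(0)
    X <- matrix(0, config$n_channels, n_ep * ep_len)
    for (e in seq_len(n_ep)) {
      ep <- draw_epoch_labels(ep_len, proc, config$duration_shape,
                              config$sfreq)
      carriers <- vapply(seq_len(K), function(m) {
        band_carrier(ep_len, config$carrier_bands[m, ], config$sfreq,
                     config$carrier_mode)
      }, numeric(ep_len))
      signs <- ifelse(stats::runif(nrow(ep$segments)) <
                        config$polarity_flip_prob, -1, 1)
      amp <- numeric(ep_len)
      for (s in seq_len(nrow(ep$segments))) {
        idx <- (ep$segments$start[s] + 1L):ep$segments$end[s]
        amp[idx] <- carriers[idx, ep$segments$map[s]] * signs[s]
      }
      off <- (e - 1L) * ep_len
      X[, off + seq_len(ep_len)] <- templates$maps[, ep$labels] *
        rep(amp, each = config$n_channels)
      ep$segments$start <- ep$segments$start + off
      ep$segments$end <- ep$segments$end + off
      ep$segments$sign <- signs
      lab_all <- c(lab_all, ep$labels)
      seg_all <- rbind(seg_all, ep$segments)
      sgn_all <- c(sgn_all, signs)
    }
    if (is.finite(config$snr)) {
      rms_sig <- sqrt(mean(X^2))
      X <- X + matrix(stats::rnorm(length(X), sd = rms_sig / config$snr),
                      nrow = nrow(X))
    }
    bounds <- cbind(start = (seq_len(n_ep) - 1L) * ep_len,
                    end = seq_len(n_ep) * ep_len)
    rec <- eeg_recording(X, config$sfreq,
                         positions = fibonacci_sphere(config$n_channels),
                         epochs = bounds)
    list(recording = rec,
         truth = list(templates = templates, labels = lab_all,
                      segments = seg_all, coverage = condition_coverage,
                      carrier_bands = config$carrier_bands,
                      signs = sgn_all))
  })
}

#' Two-condition group design
#'
#' Describes a paired two-condition study with a planted coverage shift: on
#' each `effect_map`, condition 1 minus condition 2 coverage differs by
#' `sign * delta`.  Signs must sum to zero so both coverage vectors keep
#' summing to 1 (the classic double dissociation uses `+1` on one map and
#' `-1` on another).
#'
#' @param n_subjects number of subjects.
#' @param conditions two condition tags.
#' @param base_coverage length-K coverage vector shared by both conditions
#'   before the shift (default uniform).
#' @param effect_maps map indices carrying the planted effect.
#' @param effect_signs `+1`/`-1` per effect map; must sum to 0.
#' @param delta coverage shift in `[0, 1)`.
#' @param jitter_corr target spatial correlation between each subject's
#'   templates and the group templates.
#' @param K number of maps (needed when `base_coverage` is default).
#' @return a `group_design` list.
#' @export
group_design <- function(n_subjects = 20L, conditions = c("DE", "NE"),
                         base_coverage = NULL, effect_maps = c(3L, 4L),
                         effect_signs = c(1, -1), delta = 0.10,
                         jitter_corr = 0.9, K = 5L) {
  if (length(conditions) != 2L) stopf("exactly two conditions required")
  if (is.null(base_coverage)) base_coverage <- rep(1 / K, K)
  K <- length(base_coverage)
  if (length(effect_maps) != length(effect_signs) ||
      abs(sum(effect_signs)) > 1e-12) {
    stopf("effect signs must pair up and sum to zero")
  }
  shift <- numeric(K)
  shift[effect_maps] <- effect_signs * delta / 2
  cov1 <- base_coverage + shift
  cov2 <- base_coverage - shift
  if (any(cov1 < 0) || any(cov1 > 1) || any(cov2 < 0) || any(cov2 > 1)) {
    stopf("delta = %g drives a coverage outside [0, 1]", delta)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 conditions = as.character(conditions),
                 coverage = rbind(cov1, cov2), effect_maps = effect_maps,
                 effect_signs = effect_signs, delta = delta,
                 jitter_corr = jitter_corr, K = K),
            class = "group_design")
}

# Jitter one template set to an exact target correlation with the original:
# add a unit perturbation orthogonal to each map (within the zero-mean
# subspace) with weight eps = sqrt(1/rho^2 - 1), renormalize.
jitter_templates <- function(templates, rho) {
  m <- templates$maps
  if (rho >= 1) return(templates)
  eps <- sqrt(1 / rho^2 - 1)
  out <- m
  for (k in seq_len(ncol(m))) {
    z <- stats::rnorm(nrow(m))
    z <- z - mean(z)
    z <- z - sum(z * m[, k]) * m[, k]
    z <- z / sqrt(sum(z^2))
    out[, k] <- (m[, k] + eps * z) / sqrt(1 + eps^2)
  }
  template_set(out, provenance = "subject")
}

#' Simulate a paired two-condition group
#'
#' Each subject receives a jittered copy of the group templates (exact
#' target correlation `design$jitter_corr` with each group map) and one
#' recording per condition, with planted coverage vectors differing exactly
#' by the design's shift on the effect maps.  All randomness derives from
#' `config$seed`.
#'
#' @param design a [group_design()].
#' @param config a [generator_config()] with `n_maps == design$K`.
#' @return list with `group_templates`, `subjects` (per subject: `templates`
#'   plus one `simulate_recording()` result per condition), and the design.
#' @export
simulate_group <- function(design, config) {
  stopifnot(inherits(design, "group_design"),
            inherits(config, "generator_config"))
  if (config$n_maps != design$K) stopf("config and design disagree on K")
  group_templates <- make_templates(config$n_channels, config$n_maps,
                                    config$seed,
                                    config$template_min_separation)
  subjects <- vector("list", design$n_subjects)
  for (s in seq_len(design$n_subjects)) {
    subj_templates <- with_seed(derive_seed(config$seed, s, 0L),
                                jitter_templates(group_templates,
                                                 design$jitter_corr))
    runs <- list()
    for (ci in 1:2) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, s, ci)
      runs[[design$conditions[ci]]] <-
        simulate_recording(cfg, subj_templates, design$coverage[ci, ])
      runs[[design$conditions[ci]]]$recording$condition <-
        design$conditions[ci]
    }
    subjects[[s]] <- list(templates = subj_templates, runs = runs)
  }
  list(group_templates = group_templates, subjects = subjects,
       design = design)
}

derive_seed <- function(seed, a, b) {
  as.integer((as.numeric(seed) * 7919 + a * 104729 + b * 1299709) %%
               2147483647)
}

#' Single-sphere toy lead field
#'
#' Analytic forward model for current dipoles inside a homogeneous unit
#' conducting sphere with electrodes on its surface, evaluated by the
#' classical Legendre-series expansion (truncated at degree `nmax`).  The
#' gain matrix has one column per source and Cartesian moment component
#' (x, y, z), average-referenced across channels.  Sources must lie
#' strictly inside the sphere; a source at the exact centre (no radial
#' direction) is emitted as zero columns and flagged degenerate.
#'
#' @param n_channels number of electrodes (Fibonacci-lattice montage on the
#'   unit sphere).
#' @param n_sources number of source points; ignored if `source_positions`
#'   is given.
#' @param seed RNG seed for random source placement (uniform in the
#'   spherical shell of radius 0.3-0.85).
#' @param source_positions optional n x 3 matrix of source coordinates.
#' @param nmax Legendre truncation degree.
#' @return a `leadfield` list: `gain` (channels x 3 n_sources),
#'   `source_positions`, `channel_positions`, `degenerate` (logical per
#'   source).
#' @export
toy_leadfield <- function(n_channels = 64L, n_sources = 300L, seed = 1L,
                          source_positions = NULL, nmax = 300L) {
  if (is.null(source_positions)) {
    if (!is_count(n_sources)) stopf("need n_sources >= 1")
    source_positions <- with_seed(seed, {
      r <- stats::runif(n_sources, 0.3^3, 0.85^3)^(1 / 3)
      u <- matrix(stats::rnorm(3L * n_sources), ncol = 3L)
      u <- u / sqrt(rowSums(u^2))
      u * r
    })
  }
  source_positions <- matrix(as.numeric(source_positions), ncol = 3L)
  n_src <- nrow(source_positions)
  elec <- fibonacci_sphere(n_channels)
  b <- sqrt(rowSums(source_positions^2))
  if (any(b >= 1)) stopf("source on or outside the sphere")
  gain <- matrix(0, n_channels, 3L * n_src)
  degenerate <- b < 1e-9
  n <- seq_len(nmax)
  for (j in which(!degenerate)) {
    p_hat <- source_positions[j, ] / b[j]
    c_ang <- pmin(1, pmax(-1, as.vector(elec %*% p_hat)))
    leg <- legendre_table(c_ang, nmax)
    k_n <- (2 * n + 1) / n * b[j]^(n - 1) / (4 * pi)
    S1 <- leg$p %*% (k_n * n)    # radial series
    S2 <- leg$dp %*% k_n         # tangential series
    cols <- (3L * (j - 1L) + 1L):(3L * j)
    for (d in 1:3) {
      gain[, cols[d]] <- p_hat[d] * S1 + elec[, d] * S2 - p_hat[d] * c_ang * S2
    }
  }
  gain <- center_cols(gain)
  structure(list(gain = gain, source_positions = source_positions,
                 channel_positions = elec, degenerate = degenerate),
            class = "leadfield")
}
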