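# Shared small fixtures, built in code at test time.

fix_templates <- function(n_channels = 16, K = 3, seed = 11, sep = 0.5) {
  make_templates(n_channels, K, seed = seed, template_min_separation = sep)
}

fix_recording <- function(n_channels = 16, K = 3, seed = 21, snr = 4,
                          epoch_length = 4, n_epochs = 2, sfreq = 250, ...) {
  ts <- fix_templates(n_channels, K, seed = seed)
  cfg <- generator_config(n_channels = n_channels, sfreq = sfreq, n_maps = K,
                          epoch_length = epoch_length, n_epochs = n_epochs,
                          snr = snr, seed = seed + 1, ...)
  simulate_recording(cfg, ts)
}

# Peak-map matrix sampled exactly from templates with per-map amplitudes
# and optional noise; returns maps plus generating labels.
fix_peak_maps <- function(templates, n = 60, seed = 31, noise_sd = 0) {
  maps <- templates$maps
  K <- ncol(maps)
  set.seed(seed)
  labels <- sample.int(K, n, replace = TRUE)
  amp <- runif(n, 0.5, 2)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  X <- maps[, labels] * rep(amp * sgn, each = nrow(maps))
  if (noise_sd > 0) X <- X + matrix(rnorm(length(X), sd = noise_sd),
                                    nrow = nrow(X))
  list(maps = X, labels = labels)
}
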