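#' Spectral analysis configuration
#'
#' @param f_start,f_stop,f_step frequency grid in Hz (default 1-40 Hz at
#'   0.5 Hz, covering the five canonical bands).
#' @param fwhm1 time-domain full width at half maximum of the mother
#'   wavelet at 1 Hz, seconds; the wavelet scales as `fwhm1 / f` at
#'   frequency f.
#' @param bands named list of `[lo, hi]` band edges, Hz.  Defaults to
#'   Delta 1-4, Theta 4.5-8, Alpha 8.5-12, Beta 12.5-25, Gamma 25.5-40.
#' @return a `spectral_config` list.
#' @export
spectral_config <- function(f_start = 1, f_stop = 40, f_step = 0.5,
                            fwhm1 = 3,
                            bands = list(Delta = c(1, 4),
                                         Theta = c(4.5, 8),
                                         Alpha = c(8.5, 12),
                                         Beta = c(12.5, 25),
                                         Gamma = c(25.5, 40))) {
  if (f_step <= 0) stopf("f_step must be positive")
  freqs <- seq(f_start, f_stop, by = f_step)
  edges <- do.call(rbind, bands)
  if (any(edges[, 1] > edges[, 2])) stopf("band lo > hi")
  ov <- edges[order(edges[, 1]), , drop = FALSE]
  if (nrow(ov) > 1L && any(ov[-1L, 1] <= ov[-nrow(ov), 2] - 1e-9)) {
    stopf("bands must not overlap")
  }
  if (min(edges) < f_start - 1e-9 || max(edges) > f_stop + 1e-9) {
    stopf("bands must lie within the frequency grid")
  }
  structure(list(freqs = freqs, fwhm1 = fwhm1, bands = bands),
            class = "spectral_config")
}

#' Morlet wavelet time-frequency power
#'
#' Complex Morlet convolution per channel and frequency (FFT-based,
#' zero-padded, per epoch); power is the squared magnitude.  The Gaussian
#' envelope of the wavelet at frequency f has time-domain FWHM
#' `fwhm1 / f` seconds.  Samples within one half-width (FWHM/2) of an
#' epoch edge are flagged per frequency and excluded from downstream
#' band-power summaries rather than mirrored, to avoid biasing
#' label-conditioned averages.
#'
#' @param rec an [eeg_recording()].
#' @param config a [spectral_config()].
#' @return a `tf_power` list: `power` (channels x frequencies x time, in
#'   squared input units), `freqs`, `edge` (frequencies x time logical
#'   flag), `sfreq`, `config`.
#' @export
morlet_tf <- function(rec, config = spectral_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  freqs <- config$freqs
  if (max(freqs) >= rec$sfreq / 2) {
    stopf("max frequency must be below Nyquist")
  }
  nc <- nrow(rec$data)
  nt <- ncol(rec$data)
  power <- array(0, dim = c(nc, length(freqs), nt))
  edge <- matrix(FALSE, length(freqs), nt)
  for (idx in epoch_indices(rec)) {
    n <- length(idx)
    # wavelet support: +-3 SD of the widest (lowest-frequency) envelope
    sigma_max <- config$fwhm1 / min(freqs) / (2 * sqrt(2 * log(2)))
    half_max <- ceiling(3 * sigma_max * rec$sfreq)
    support <- ceiling(config$fwhm1 / min(freqs) * rec$sfreq)
    if (n < support) {
      stopf("epoch of %d samples shorter than the %g-Hz wavelet FWHM (%d samples)",
            n, min(freqs), support)
    }
    nfft <- stats::nextn(n + 2L * half_max, 2L)
    Xpad <- cbind(rec$data[, idx, drop = FALSE], matrix(0, nc, nfft - n))
    Xf <- stats::mvfft(t(Xpad))                       # nfft x channels
    tvec <- c(seq(0, by = 1, length.out = nfft %/% 2 + 1L),
              seq(-(nfft - nfft %/% 2 - 1L), -1)) / rec$sfreq
    for (fi in seq_along(freqs)) {
      f <- freqs[fi]
      sigma <- config$fwhm1 / f / (2 * sqrt(2 * log(2)))
      w <- exp(-tvec^2 / (2 * sigma^2)) * exp(2i * pi * f * tvec)
      w <- w / (sigma * sqrt(2 * pi) * rec$sfreq)     # unit-gain envelope
      Wf <- stats::fft(w)
      conv <- stats::mvfft(Xf * Wf, inverse = TRUE) / nfft
      power[, fi, idx] <- 2 * t(Mod(conv[seq_len(n), , drop = FALSE])^2)
      half <- ceiling((config$fwhm1 / f / 2) * rec$sfreq)
      flag <- rep(FALSE, n)
      flag[seq_len(min(half, n))] <- TRUE
      flag[seq.int(max(1L, n - half + 1L), n)] <- TRUE
      edge[fi, idx] <- flag
    }
  }
  structure(list(power = power, freqs = freqs, edge = edge,
                 sfreq = rec$sfreq, config = config),
            class = "tf_power")
}

#' Band power per microstate
#'
#' For each map and frequency band: the mean power over all time points
#' labelled with that map, over the band's frequency bins, and over all
#' channels.  Edge-flagged samples are excluded per frequency; maps with
#' zero presence yield `NA`.
#'
#' @param tfp a `tf_power` from [morlet_tf()].
#' @param labels label vector aligned with the time axis (see
#'   [backfit_labels()]).
#' @param K number of maps (defaults to the largest label).
#' @return data.frame `map, band, power` (mean squared input units).
#' @export
band_power_by_microstate <- function(tfp, labels, K = NULL) {
  stopifnot(inherits(tfp, "tf_power"))
  if (length(labels) != dim(tfp$power)[3L]) {
    stopf("labels not aligned with the time axis")
  }
  if (is.null(K)) K <- max(labels, na.rm = TRUE)
  bands <- tfp$config$bands
  out <- expand.grid(map = seq_len(K), band = names(bands),
                     stringsAsFactors = FALSE)
  out$power <- NA_real_
  for (bi in seq_along(bands)) {
    fsel <- which(tfp$freqs >= bands[[bi]][1] - 1e-9 &
                    tfp$freqs <= bands[[bi]][2] + 1e-9)
    for (k in seq_len(K)) {
      tsel <- which(!is.na(labels) & labels == k)
      if (!length(tsel)) next
      vals <- numeric(0)
      for (fi in fsel) {
        tt <- tsel[!tfp$edge[fi, tsel]]
        if (length(tt)) vals <- c(vals, as.vector(tfp$power[, fi, tt]))
      }
      if (length(vals)) {
        out$power[out$map == k & out$band == names(bands)[bi]] <- mean(vals)
      }
    }
  }
  out
}
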