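#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`) to
#' each channel, separately per epoch so that filter transients never bleed
#' across concatenation boundaries.  Zero-phase filtering avoids distorting
#' the instantaneous topographies the microstate analysis depends on.  The
#' per-channel DC offset of each epoch is removed first.
#'
#' @param rec an [eeg_recording()].
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi < sfreq/2`.
#' @param order Butterworth order (of the underlying one-pass filter).
#' @return the filtered recording.
#' @export
bandpass_filter <- function(rec, f_lo, f_hi, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(f_lo > 0 && f_lo < f_hi && f_hi < rec$sfreq / 2)) {
    stopf("need 0 < f_lo < f_hi < sfreq/2 (got %g, %g at %g Hz)",
          f_lo, f_hi, rec$sfreq)
  }
  bf <- signal::butter(order, c(f_lo, f_hi) / (rec$sfreq / 2), type = "pass")
  warmup <- 3L * (2L * order + 1L)
  for (idx in epoch_indices(rec)) {
    if (length(idx) <= warmup) {
      stopf("epoch of %d samples is shorter than the filter warm-up (%d)",
            length(idx), warmup)
    }
    seg <- rec$data[, idx, drop = FALSE]
    seg <- seg - rowMeans(seg)
    rec$data[, idx] <- t(apply(seg, 1L, function(ch) {
      signal::filtfilt(bf, ch)
    }))
  }
  rec
}

#' Downsample a recording
#'
#' Anti-alias low-pass (zero-phase Butterworth at 80% of the target Nyquist)
#' followed by decimation.  The original rate must be an integer multiple of
#' the target; epoch boundaries are rescaled consistently.
#'
#' @param rec an [eeg_recording()].
#' @param target_sfreq new sampling rate, Hz.
#' @return the downsampled recording.
#' @export
downsample <- function(rec, target_sfreq) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_sfreq > rec$sfreq) {
    stopf("target rate %g Hz above original %g Hz", target_sfreq, rec$sfreq)
  }
  if (target_sfreq == rec$sfreq) return(rec)
  q <- rec$sfreq / target_sfreq
  if (abs(q - round(q)) > 1e-9) {
    stopf("original rate must be an integer multiple of the target")
  }
  q <- as.integer(round(q))
  lp <- signal::butter(8L, 0.8 / q, type = "low")
  new_epochs <- NULL
  pieces <- list()
  off <- 0L
  for (e in seq_len(nrow(rec$epochs))) {
    idx <- (rec$epochs[e, "start"] + 1L):rec$epochs[e, "end"]
    seg <- rec$data[, idx, drop = FALSE]
    filt <- t(apply(seg, 1L, function(ch) signal::filtfilt(lp, ch)))
    keep <- seq(1L, ncol(filt), by = q)
    pieces[[e]] <- filt[, keep, drop = FALSE]
    new_epochs <- rbind(new_epochs, c(off, off + length(keep)))
    off <- off + length(keep)
  }
  eeg_recording(do.call(cbind, pieces), target_sfreq,
                channels = rec$channels, positions = rec$positions,
                epochs = new_epochs, condition = rec$condition)
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces the listed channels with Perrin-type 3-D spherical-spline
#' estimates from the remaining channels (spline order m = 4, Legendre
#' series truncated at degree 50, Tikhonov regularization 1e-5).  Good
#' channels are untouched.
#'
#' @param rec an [eeg_recording()] with channel positions.
#' @param bad_channel_ids character vector of channel ids to rebuild.
#' @param m spline order.
#' @param lambda regularization added to the spline system's diagonal.
#' @param nmax maximum Legendre degree.
#' @return the recording with bad channels replaced.
#' @export
interpolate_bad_channels <- function(rec, bad_channel_ids, m = 4L,
                                     lambda = 1e-5, nmax = 50L) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad_channel_ids) == 0L) return(rec)
  if (is.null(rec$positions)) stopf("channel positions required")
  bad <- match(bad_channel_ids, rec$channels)
  if (anyNA(bad)) {
    stopf("unknown channel id(s): %s",
          paste(bad_channel_ids[is.na(bad)], collapse = ", "))
  }
  if (length(bad) >= nrow(rec$data) / 2) {
    stopf("refusing to interpolate %d of %d channels", length(bad),
          nrow(rec$data))
  }
  good <- setdiff(seq_len(nrow(rec$data)), bad)
  pos <- rec$positions / sqrt(rowSums(rec$positions^2))
  if (all(pos[good, 3] > 0) || all(pos[good, 3] < 0)) {
    warning("all good channels lie in one hemisphere; spline system may be ",
            "ill-conditioned (regularized solve applied)")
  }
  G_gg <- spline_g(pos[good, , drop = FALSE] %*% t(pos[good, , drop = FALSE]),
                   m, nmax)
  G_bg <- spline_g(pos[bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE]),
                   m, nmax)
  ng <- length(good)
  # Perrin 1989 system with the constant term; regularized on the diagonal.
  A <- rbind(cbind(G_gg + diag(lambda, ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(rec$data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  rec$data[bad, ] <- cbind(G_bg, rep(1, length(bad))) %*% sol
  rec
}

# Perrin g(cos gamma) kernel: sum_n (2n+1) / (n (n+1))^m P_n(x) / (4 pi).
spline_g <- function(cosang, m, nmax) {
  x <- pmin(1, pmax(-1, as.vector(cosang)))
  n <- seq_len(nmax)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  P <- legendre_table(x, nmax)$p
  matrix(P %*% coef / (4 * pi), nrow = nrow(cosang))
}

#' Extract fixed-length epochs
#'
#' `mode = "pre-event"` takes, for each event, the window of
#' `epoch_length_s` seconds ending at the event sample.  `mode = "random"`
#' draws `count` non-overlapping windows uniformly (seeded).  The selected
#' windows are concatenated into a new recording whose `epochs` field marks
#' the boundaries.
#'
#' @param rec an [eeg_recording()].
#' @param events data.frame with column `sample` (0-based), as from
#'   [read_events()]; used by `"pre-event"` mode.
#' @param epoch_length_s epoch length in seconds.
#' @param mode `"pre-event"` or `"random"`.
#' @param count number of random epochs (`"random"` mode).
#' @param seed RNG seed (`"random"` mode).
#' @return an [eeg_recording()] of concatenated epochs.
#' @export
extract_epochs <- function(rec, events = NULL, epoch_length_s,
                           mode = c("pre-event", "random"),
                           count = NULL, seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  mode <- match.arg(mode)
  len <- as.integer(round(epoch_length_s * rec$sfreq))
  n <- ncol(rec$data)
  if (mode == "pre-event") {
    if (is.null(events) || nrow(events) == 0L) stopf("events required")
    starts <- sort(as.integer(events$sample)) - len
    if (any(starts < 0L)) {
      stopf("requested window extends before recording start")
    }
  } else {
    if (!is_count(count)) stopf("`count` required for random mode")
    if (is.null(seed)) stopf("`seed` required for random mode")
    n_slots <- n %/% len
    if (count > n_slots) {
      stopf("cannot place %d non-overlapping %d-sample epochs in %d samples",
            count, len, n)
    }
    slots <- with_seed(seed, sort(sample.int(n_slots, count)))
    starts <- (slots - 1L) * len
  }
  pieces <- lapply(starts, function(s) rec$data[, (s + 1L):(s + len),
                                                drop = FALSE])
  bounds <- cbind(start = (seq_along(starts) - 1L) * len,
                  end = seq_along(starts) * len)
  eeg_recording(do.call(cbind, pieces), rec$sfreq, channels = rec$channels,
                positions = rec$positions, epochs = bounds,
                condition = rec$condition)
}
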