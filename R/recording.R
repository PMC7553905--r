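#' Multichannel EEG recording container
#'
#' Bundles a channels x time sample matrix (microvolts) with its sampling
#' rate, channel identifiers, optional unit-sphere channel positions, epoch
#' boundaries and a condition tag.  Epoch boundaries use 0-based, half-open
#' sample intervals `[start, end)`, matching the package's on-disk formats;
#' helper [epoch_indices()] converts them to 1-based R indices.
#'
#' @param data numeric matrix, channels x time, in microvolts.
#' @param sfreq sampling rate in Hz.
#' @param channels character vector of channel ids (defaults to
#'   `"E1".."En"`).
#' @param positions optional n_channels x 3 matrix of unit-sphere sensor
#'   coordinates.
#' @param epochs integer matrix with columns `start`, `end` (0-based,
#'   half-open).  Defaults to one epoch spanning the whole recording.
#' @param condition optional condition label (e.g. `"DE"`, `"NE"`).
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, channels = NULL, positions = NULL,
                          epochs = NULL, condition = NA_character_) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stopf("`data` must be a numeric channels x time matrix")
  }
  if (!is.numeric(sfreq) || length(sfreq) != 1L || sfreq <= 0) {
    stopf("`sfreq` must be a single positive number (Hz)")
  }
  nc <- nrow(data)
  if (is.null(channels)) channels <- paste0("E", seq_len(nc))
  if (length(channels) != nc) {
    stopf("channel-count mismatch: %d ids for %d data rows",
          length(channels), nc)
  }
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nc || ncol(positions) != 3L) {
      stopf("channel-count mismatch: positions must be %d x 3", nc)
    }
    nrm <- sqrt(rowSums(positions^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stopf("channel positions must lie on the unit sphere")
    }
    rownames(positions) <- channels
  }
  if (is.null(epochs)) epochs <- cbind(start = 0L, end = ncol(data))
  epochs <- matrix(as.integer(epochs), ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
  validate_epochs(epochs, ncol(data))
  rownames(data) <- channels
  structure(
    list(data = data, sfreq = sfreq, channels = as.character(channels),
         positions = positions, epochs = epochs,
         condition = as.character(condition)),
    class = "eeg_recording")
}

validate_epochs <- function(epochs, n_samples) {
  if (nrow(epochs) == 0L) stopf("recording needs at least one epoch")
  if (any(epochs[, "end"] <= epochs[, "start"])) {
    stopf("epochs must be non-empty half-open intervals")
  }
  if (any(epochs[, "start"] < 0L) || any(epochs[, "end"] > n_samples)) {
    stopf("epoch boundaries outside the recording")
  }
  if (nrow(epochs) > 1L) {
    ord <- order(epochs[, "start"])
    if (any(ord != seq_len(nrow(epochs)))) stopf("epochs must be ordered")
    if (any(epochs[-nrow(epochs), "end"] > epochs[-1L, "start"])) {
      stopf("epochs overlap")
    }
  }
  invisible(epochs)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d epoch%s%s\n",
    nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
    nrow(x$epochs), if (nrow(x$epochs) == 1L) "" else "s",
    if (is.na(x$condition)) "" else paste0(", condition ", x$condition)))
  invisible(x)
}

#' Epoch sample indices
#'
#' @param rec an [eeg_recording()].
#' @return list of 1-based integer index vectors, one per epoch.
#' @export
epoch_indices <- function(rec) {
  lapply(seq_len(nrow(rec$epochs)), function(i) {
    (rec$epochs[i, "start"] + 1L):rec$epochs[i, "end"]
  })
}

#' Re-reference a recording to the common average
#'
#' Subtracts, at every time point, the mean over channels, so each column of
#' the sample matrix sums to zero.  Idempotent and invariant to adding a
#' common offset to all channels.
#'
#' @param rec an [eeg_recording()].
#' @return the recording, average-referenced.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$data <- sweep(rec$data, 2L, colMeans(rec$data), "-")
  rec
}
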