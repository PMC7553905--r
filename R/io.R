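#' Read an EEG recording from disk
#'
#' Two dialects are supported.  `"delim"` is the package's plain-text
#' format: header lines `# sfreq=`, `# channels=`, optionally `# epochs=`
#' (semicolon-separated `start:end` 0-based half-open pairs) and
#' `# condition=`, followed by one tab-separated row per channel whose first
#' field is the channel id.  Values are written with 17 significant digits,
#' so write/read round-trips are bit-exact.  `"edf"` reads continuous
#' 16-bit European Data Format files (all signals at one sampling rate).
#'
#' @param path file to read.
#' @param format `"delim"` or `"edf"`.
#' @param montage optional path to a montage file with one `id x y z` line
#'   per channel (unit-sphere positions).  Channel counts must match.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path, format = c("delim", "edf"), montage = NULL) {
  format <- match.arg(format)
  rec <- if (format == "delim") read_recording_delim(path) else read_edf(path)
  if (!is.null(montage)) {
    pos <- read_montage(montage)
    if (nrow(pos) != nrow(rec$data)) {
      stopf("channel-count mismatch: montage lists %d positions for %d channels",
            nrow(pos), nrow(rec$data))
    }
    rec$positions <- as.matrix(pos[, c("x", "y", "z")])
    rownames(rec$positions) <- rec$channels
  }
  rec
}

#' Write an EEG recording (delimited dialect)
#'
#' @param rec an [eeg_recording()].
#' @param path output file.
#' @param montage optional path; if given, channel positions are written
#'   there as `id x y z` lines.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, montage = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  hdr <- c(sprintf("# sfreq=%s", fmt_num(rec$sfreq)),
           sprintf("# channels=%d", nrow(rec$data)),
           sprintf("# epochs=%s", paste(sprintf("%d:%d", rec$epochs[, 1],
                                                rec$epochs[, 2]),
                                        collapse = ";")))
  if (!is.na(rec$condition)) {
    hdr <- c(hdr, sprintf("# condition=%s", rec$condition))
  }
  rows <- vapply(seq_len(nrow(rec$data)), function(i) {
    paste(c(rec$channels[i], fmt_num(rec$data[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  if (!is.null(montage)) {
    if (is.null(rec$positions)) stopf("recording has no channel positions")
    writeLines(paste(rec$channels, fmt_num(rec$positions[, 1]),
                     fmt_num(rec$positions[, 2]), fmt_num(rec$positions[, 3])),
               montage)
  }
  invisible(path)
}

fmt_num <- function(x) sprintf("%.17g", x)

read_recording_delim <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "# ")
  hdr <- sub("^# ", "", lines[is_hdr])
  kv <- strsplit(hdr, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, function(p) paste(p[-1L], collapse = "="), "")
  if (!"sfreq" %in% keys) stopf("missing sampling rate in header")
  sfreq <- as.numeric(vals[keys == "sfreq"][1L])
  body <- lines[!is_hdr]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  data <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1L])))
  if ("channels" %in% keys &&
      as.integer(vals[keys == "channels"][1L]) != nrow(data)) {
    stopf("channel-count mismatch: header says %s, file has %d rows",
          vals[keys == "channels"][1L], nrow(data))
  }
  epochs <- NULL
  if ("epochs" %in% keys) {
    pairs <- strsplit(strsplit(vals[keys == "epochs"][1L], ";")[[1L]], ":")
    epochs <- cbind(start = as.integer(vapply(pairs, `[`, "", 1L)),
                    end = as.integer(vapply(pairs, `[`, "", 2L)))
  }
  cond <- if ("condition" %in% keys) vals[keys == "condition"][1L] else NA
  eeg_recording(data, sfreq, channels = ids, epochs = epochs,
                condition = cond)
}

read_montage <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("id", "x", "y", "z"),
                           colClasses = c("character", rep("numeric", 3)))
  tab
}

# ---- EDF -------------------------------------------------------------------

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  chr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  chr(8)                              # version
  chr(80); chr(80); chr(8); chr(8)    # patient, recording, date, time
  chr(8)                              # header bytes
  chr(44)                             # reserved
  n_rec <- as.integer(chr(8))
  rec_dur <- as.numeric(chr(8))
  ns <- as.integer(chr(4))
  field <- function(w) vapply(seq_len(ns), function(i) chr(w), "")
  labels <- field(16)
  field(80); field(8)                 # transducer, dimension
  pmin <- as.numeric(field(8)); pmax <- as.numeric(field(8))
  dmin <- as.numeric(field(8)); dmax <- as.numeric(field(8))
  field(80)                           # prefiltering
  spr <- as.integer(field(8))         # samples per record
  field(32)                           # reserved
  if (length(unique(spr)) != 1L) {
    stopf("EDF signals with mixed sampling rates are not supported")
  }
  if (is.na(rec_dur) || rec_dur <= 0) stopf("missing sampling rate in EDF header")
  sfreq <- spr[1L] / rec_dur
  raw <- readBin(con, "integer", n = n_rec * ns * spr[1L], size = 2L,
                 signed = TRUE, endian = "little")
  # records are [rec][signal][sample]
  arr <- array(raw, dim = c(spr[1L], ns, n_rec))
  data <- matrix(0, ns, spr[1L] * n_rec)
  scale <- (pmax - pmin) / (dmax - dmin)
  for (s in seq_len(ns)) {
    data[s, ] <- as.vector(arr[, s, ]) * scale[s] +
      (pmin[s] - dmin[s] * scale[s])
  }
  eeg_recording(data, sfreq, channels = labels)
}

# Minimal EDF writer (continuous, one data record per second).  Used to
# build synthetic EDF fixtures in tests; quantizes to 16 bit.
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  spr <- as.integer(round(rec$sfreq))
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec * spr != ncol(rec$data)) {
    stopf("EDF writer needs a whole number of 1-s records")
  }
  ns <- nrow(rec$data)
  pmin <- floor(apply(rec$data, 1, min)); pmax <- ceiling(apply(rec$data, 1, max))
  pmax[pmax <= pmin] <- pmin[pmax <= pmin] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    x <- as.character(x)
    formatC(substr(x, 1, w), width = w, flag = "-")
  }
  hdr <- paste0(pad("0", 8), pad("X", 80), pad("X", 80),
                pad("01.01.00", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44),
                pad(n_rec, 8), pad("1", 8), pad(ns, 4))
  sig <- paste0(paste(pad(rec$channels, 16), collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad("uV", 8), ns), collapse = ""),
                paste(pad(pmin, 8), collapse = ""),
                paste(pad(pmax, 8), collapse = ""),
                paste(rep(pad(dmin, 8), ns), collapse = ""),
                paste(rep(pad(dmax, 8), ns), collapse = ""),
                paste(rep(pad("", 80), ns), collapse = ""),
                paste(rep(pad(spr, 8), ns), collapse = ""),
                paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig), con, eos = NULL)
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- as.integer(round((rec$data[s, idx] - pmin[s]) * scale[s] + dmin))
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

# ---- event lists, labels, templates, lead fields ---------------------------

#' Read / write event lists
#'
#' Events are `sample,tag` pairs (0-based sample index, condition tag) in
#' delimited text.
#'
#' @param path file path.
#' @return data.frame with columns `sample` (integer) and `tag` (character).
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, header = FALSE, col.names = c("sample", "tag"),
                        colClasses = c("integer", "character"))
  ev
}

#' @rdname read_events
#' @param events data.frame with columns `sample`, `tag`.
#' @export
write_events <- function(events, path) {
  utils::write.table(events[, c("sample", "tag")], path, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write label sequences (run-length encoded)
#'
#' One `start_sample,end_sample,map_index` line per run, 0-based half-open.
#' Unlabelled stretches (undefined topography) are simply absent.
#'
#' @param labels integer vector of per-sample map indices (NA = undefined).
#' @param path file path.
#' @return `read_labels`: integer vector of length `n_samples`.
#' @export
write_labels <- function(labels, path) {
  r <- rle(ifelse(is.na(labels), -1L, as.integer(labels)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values >= 0L
  writeLines(sprintf("%d,%d,%d", starts[keep], ends[keep], r$values[keep]),
             path)
  invisible(path)
}

#' @rdname write_labels
#' @param n_samples total length of the decoded label vector.
#' @export
read_labels <- function(path, n_samples) {
  tab <- utils::read.csv(path, header = FALSE,
                         col.names = c("start", "end", "map"))
  out <- rep(NA_integer_, n_samples)
  for (i in seq_len(nrow(tab))) {
    out[(tab$start[i] + 1L):tab$end[i]] <- tab$map[i]
  }
  out
}

#' Read / write microstate template sets
#'
#' Delimited matrix, channels in rows, one column per map, with a header
#' line naming the map ids.
#'
#' @param templates a `template_set` or plain channels x K matrix.
#' @param path file path.
#' @export
write_templates <- function(templates, path) {
  m <- if (inherits(templates, "template_set")) templates$maps else templates
  utils::write.table(
    as.data.frame(m, optional = TRUE), path, sep = "\t",
    row.names = FALSE, col.names = colnames(m) %||% paste0("map", seq_len(ncol(m))),
    quote = FALSE)
  invisible(path)
}

#' @rdname write_templates
#' @export
read_templates <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  template_set(m)
}
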