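#' Winner-takes-all back-fitting
#'
#' Labels every time point of a recording with the template of highest
#' absolute spatial correlation.  All samples are labelled (no
#' correlation-threshold rejection) unless `min_abs_corr` is set; ties
#' break toward the lowest map id; zero-variance time points receive `NA`
#' (undefined) and are excluded from all metrics.
#'
#' @param rec an average-referenced [eeg_recording()].
#' @param templates a [template_set()].
#' @param min_abs_corr optional threshold below which a sample stays
#'   unlabelled (default `0`, i.e. pure winner-takes-all).
#' @return integer vector of map indices (length = samples; `NA` =
#'   undefined), with the recording's epoch boundaries as attribute
#'   `"epochs"`.
#' @export
backfit_labels <- function(rec, templates, min_abs_corr = 0) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(templates, "template_set"))
  X <- center_cols(rec$data)
  nrm <- sqrt(colSums(X^2))
  ok <- nrm > 0
  r_abs <- matrix(0, templates$K, ncol(X))
  r_abs[, ok] <- abs(crossprod(templates$maps,
                               sweep(X[, ok, drop = FALSE], 2L, nrm[ok], "/")))
  labels <- max.col(t(r_abs), ties.method = "first")
  best <- r_abs[cbind(labels, seq_along(labels))]
  labels[!ok | best < min_abs_corr] <- NA_integer_
  attr(labels, "epochs") <- rec$epochs
  labels
}

label_runs <- function(labels, epochs = NULL) {
  if (is.null(epochs)) epochs <- attr(labels, "epochs")
  if (is.null(epochs)) epochs <- cbind(start = 0L, end = length(labels))
  out <- NULL
  for (e in seq_len(nrow(epochs))) {
    idx <- (epochs[e, 1] + 1L):epochs[e, 2]
    r <- rle(ifelse(is.na(labels[idx]), -1L, as.integer(labels[idx])))
    ends <- cumsum(r$lengths)
    out <- rbind(out, data.frame(epoch = e, map = r$values,
                                 length = r$lengths,
                                 start = epochs[e, 1] + ends - r$lengths))
  }
  out[out$map > 0L, , drop = FALSE]
}

#' Temporal metrics of a label sequence
#'
#' A segment is a maximal run of one label within an epoch (runs never span
#' epoch boundaries).  Per map: mean duration (ms), occurrence (segments
#' per labelled second), coverage (fraction of labelled samples).  Maps
#' with zero presence get coverage and occurrence 0 and missing duration,
#' so absent states do not bias group duration means.
#'
#' @param labels integer label vector (see [backfit_labels()]); `NA` samples
#'   are excluded from the labelled time base.
#' @param sfreq sampling rate, Hz.
#' @param K number of maps (defaults to the largest label present).
#' @param epochs optional epoch matrix; defaults to the labels' attribute.
#' @return data.frame with columns `map`, `mean_duration_ms`,
#'   `occurrence_hz`, `coverage`.
#' @export
segment_statistics <- function(labels, sfreq, K = NULL, epochs = NULL) {
  runs <- label_runs(labels, epochs)
  n_labeled <- sum(!is.na(labels))
  if (is.null(K)) K <- max(runs$map, 1L)
  secs <- n_labeled / sfreq
  out <- data.frame(map = seq_len(K), mean_duration_ms = NA_real_,
                    occurrence_hz = 0, coverage = 0)
  for (k in seq_len(K)) {
    rk <- runs[runs$map == k, , drop = FALSE]
    if (nrow(rk)) {
      out$mean_duration_ms[k] <- mean(rk$length) * 1000 / sfreq
      out$occurrence_hz[k] <- nrow(rk) / secs
      out$coverage[k] <- sum(rk$length) / n_labeled
    }
  }
  out
}

#' Global explained variance of a labelled fit
#'
#' `GEV_k = sum over t labelled k of (GFP(t) * r_t)^2 / sum over all t of
#' GFP(t)^2`, where `r_t` is the spatial correlation between the sample map
#' at t and template k.  The per-map values sum to the total GEV of the
#' labelled fit.
#'
#' @param rec an average-referenced [eeg_recording()].
#' @param templates a [template_set()].
#' @param labels labels from [backfit_labels()].
#' @return numeric vector of per-map GEV (names `map1..mapK`), with the
#'   total as attribute `"total"`.
#' @export
compute_gev <- function(rec, templates, labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(labels) != ncol(rec$data)) stopf("labels/recording length mismatch")
  X <- center_cols(rec$data)
  gfp2 <- colMeans(X^2)
  denom <- sum(gfp2)
  if (denom == 0) stopf("zero total GFP power")
  nrm <- sqrt(colSums(X^2))
  ok <- which(nrm > 0 & !is.na(labels))
  r <- crossprod(templates$maps, sweep(X[, ok, drop = FALSE], 2L,
                                       nrm[ok], "/"))
  r_t <- r[cbind(labels[ok], seq_along(ok))]
  contrib <- gfp2[ok] * r_t^2
  gev <- vapply(seq_len(templates$K), function(k) {
    sum(contrib[labels[ok] == k])
  }, numeric(1)) / denom
  names(gev) <- colnames(templates$maps)
  attr(gev, "total") <- sum(gev)
  gev
}

#' Optimal correspondence between two template sets
#'
#' One-to-one assignment maximizing the summed absolute spatial
#' correlation, found by exhaustive search over permutations (template
#' counts here are small).  For unequal K the smaller set is matched into
#' the larger with a warning.
#'
#' @param templates_a,templates_b [template_set()]s (or plain matrices).
#' @return list with `matching` (for each map of `a`, the matched map of
#'   `b`, NA if unmatched), `matched_abs_corr`, and the full K_a x K_b
#'   `abs_corr` table.
#' @export
map_correspondence <- function(templates_a, templates_b) {
  A <- if (inherits(templates_a, "template_set")) templates_a$maps else
    as.matrix(templates_a)
  B <- if (inherits(templates_b, "template_set")) templates_b$maps else
    as.matrix(templates_b)
  ka <- ncol(A); kb <- ncol(B)
  if (ka != kb) warning("unequal template counts; best partial matching")
  tab <- abs(colwise_correlation(A, B))
  small <- min(ka, kb)
  if (max(ka, kb) > 8L) stopf("exhaustive matching limited to K <= 8")
  perms <- permutations(max(ka, kb))
  best <- NULL; best_val <- -Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, seq_len(small)]
    val <- if (ka <= kb) sum(tab[cbind(seq_len(small), p)]) else
      sum(tab[cbind(p, seq_len(small))])
    if (val > best_val) { best_val <- val; best <- p }
  }
  matching <- rep(NA_integer_, ka)
  if (ka <= kb) {
    matching <- as.integer(unname(best))
  } else {
    matching[best] <- seq_len(small)
  }
  matched <- ifelse(is.na(matching), NA_real_,
                    tab[cbind(seq_len(ka), matching)])
  list(matching = matching, matched_abs_corr = matched, abs_corr = tab)
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, sub + (sub >= i)))
  }
  out
}

#' Per-subject, per-condition microstate metrics table
#'
#' Back-fits group templates to one recording and returns the tidy rows
#' used by the statistics layer: one row per map with GEV, mean duration,
#' occurrence and coverage.
#'
#' @param rec an average-referenced [eeg_recording()].
#' @param templates group-level [template_set()].
#' @param subject subject identifier.
#' @param condition condition tag (defaults to the recording's).
#' @return data.frame `subject, condition, map, gev, mean_duration_ms,
#'   occurrence_hz, coverage`.
#' @export
microstate_metrics <- function(rec, templates, subject,
                               condition = rec$condition) {
  labels <- backfit_labels(rec, templates)
  seg <- segment_statistics(labels, rec$sfreq, K = templates$K)
  gev <- compute_gev(rec, templates, labels)
  data.frame(subject = subject, condition = condition, map = seg$map,
             gev = as.numeric(gev), mean_duration_ms = seg$mean_duration_ms,
             occurrence_hz = seg$occurrence_hz, coverage = seg$coverage)
}
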