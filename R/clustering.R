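#' Microstate template set
#'
#' K average-referenced, unit-L2-norm topographies, one per column.
#' Construction re-centres and re-normalizes, so the invariants hold by
#' construction.
#'
#' @param maps numeric channels x K matrix.
#' @param provenance free-text origin tag (`"subject"`, `"group"`,
#'   `"planted"`, ...).
#' @param gev optional per-map global explained variance on the source data.
#' @return a `template_set`.
#' @export
template_set <- function(maps, provenance = NA_character_, gev = NULL) {
  maps <- as.matrix(maps)
  if (ncol(maps) < 1L) stopf("need at least one map")
  nrm <- sqrt(colSums(center_cols(maps)^2))
  if (any(nrm == 0)) zero_variance_error("template map has zero variance")
  maps <- unitize_cols(maps)
  if (is.null(colnames(maps))) colnames(maps) <- paste0("map", seq_len(ncol(maps)))
  structure(list(maps = maps, K = ncol(maps), provenance = provenance,
                 gev = gev),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d maps x %d channels (%s)\n", x$K,
              nrow(x$maps), x$provenance))
  if (!is.null(x$gev)) {
    cat("  GEV:", paste(sprintf("%.3f", x$gev), collapse = " "), "\n")
  }
  invisible(x)
}

zero_variance_error <- function(msg) {
  stop(structure(class = c("sleepstates_zero_variance", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Global Field Power
#'
#' GFP(t) is the spatial standard deviation over channels of the
#' average-referenced map at time t (root mean square of the re-referenced
#' map; population convention, divisor `n_channels`).  GFP maxima mark the
#' moments of highest topographic signal-to-noise, which is why clustering
#' uses only maps at GFP peaks.
#'
#' @param x an [eeg_recording()] or channels x time matrix.
#' @return numeric vector of GFP values, one per time point.
#' @export
compute_gfp <- function(x) {
  m <- if (inherits(x, "eeg_recording")) x$data else as.matrix(x)
  sqrt(colMeans(center_cols(m)^2))
}

#' Find GFP peaks
#'
#' Local maxima of the GFP series, searched within each epoch separately so
#' concatenation boundaries never produce peaks.  A peak is a sample whose
#' GFP strictly exceeds its neighbours; for plateaus the first sample of
#' the plateau counts.  An optional minimum spacing keeps the larger peak.
#'
#' @param gfp numeric GFP series (see [compute_gfp()]).
#' @param epochs optional epoch-boundary matrix (0-based half-open rows
#'   `start,end`), or an [eeg_recording()] to take boundaries from.
#'   Default: one epoch.
#' @param min_peak_distance minimum spacing between kept peaks, in samples.
#' @return strictly increasing integer vector of 1-based peak indices
#'   (possibly empty).
#' @export
find_gfp_peaks <- function(gfp, epochs = NULL, min_peak_distance = 0L) {
  if (inherits(epochs, "eeg_recording")) epochs <- epochs$epochs
  if (is.null(epochs)) epochs <- cbind(start = 0L, end = length(gfp))
  peaks <- integer(0)
  for (e in seq_len(nrow(epochs))) {
    idx <- (epochs[e, 1] + 1L):epochs[e, 2]
    v <- gfp[idx]
    r <- rle(v)
    if (length(r$values) >= 3L) {
      run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
      interior <- 2:(length(r$values) - 1L)
      is_peak <- r$values[interior] > r$values[interior - 1L] &
        r$values[interior] > r$values[interior + 1L]
      peaks <- c(peaks, idx[run_start[interior][is_peak]])
    }
  }
  if (min_peak_distance > 0L && length(peaks) > 1L) {
    ord <- peaks[order(gfp[peaks], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) {
      if (!length(kept) || all(abs(kept - p) >= min_peak_distance)) {
        kept <- c(kept, p)
      }
    }
    peaks <- sort(kept)
  }
  peaks
}

#' Spatial correlation between two maps
#'
#' Pearson correlation across channels of the two average-referenced maps.
#' The polarity-invariant similarity used throughout the package is its
#' absolute value, since inverted polarities arise from oscillations of the
#' same generators.
#'
#' @param map_a,map_b numeric vectors of equal length.
#' @return correlation in `[-1, 1]`.
#' @export
spatial_correlation <- function(map_a, map_b) {
  if (length(map_a) != length(map_b)) stopf("maps differ in length")
  a <- map_a - mean(map_a)
  b <- map_b - mean(map_b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    zero_variance_error("spatial correlation undefined for a zero-variance map")
  }
  sum(a * b) / (na * nb)
}

#' Clustering configuration
#'
#' @param n_restarts independent seeded initializations; the run with the
#'   highest total GEV is kept.
#' @param max_iter iteration cap per run.
#' @param tol convergence tolerance on the GEV improvement.
#' @param seed RNG seed.
#' @return a `kmeans_config` list.
#' @export
kmeans_config <- function(n_restarts = 100L, max_iter = 1000L, tol = 1e-6,
                          seed = 1L) {
  stopifnot(is_count(n_restarts), is_count(max_iter), tol > 0)
  structure(list(n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "kmeans_config")
}

#' Polarity-invariant modified k-means
#'
#' Clusters maps (typically maps at GFP peaks) into K templates ignoring
#' polarity: each map is assigned to the template of highest absolute
#' spatial correlation, and each template is updated as the dominant
#' eigenvector of the sum of outer products of its assigned
#' (average-referenced, raw-amplitude) maps — the sign-invariant analogue
#' of the cluster mean.  Because raw amplitudes weight the eigenproblem,
#' each update maximizes the global explained variance (GEV) of its
#' cluster, so GEV is non-decreasing over iterations.  The best of
#' `n_restarts` seeded initializations (templates drawn from distinct input
#' maps) is returned.
#'
#' @param peak_maps numeric channels x N matrix of maps to cluster.
#' @param K number of clusters (`K <= N`).
#' @param config a [kmeans_config()].
#' @return a `microstate_fit`: `templates` (a [template_set()] with per-map
#'   GEV), `labels` (per input map), `gev` (total), `K`.
#' @export
modified_kmeans <- function(peak_maps, K, config = kmeans_config()) {
  X <- center_cols(as.matrix(peak_maps))
  N <- ncol(X)
  if (N < K) stopf("need at least K = %d maps, got %d", K, N)
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) zero_variance_error("zero-variance map among inputs")
  Xn <- sweep(X, 2L, nrm, "/")
  gfp2 <- colMeans(X^2)              # GFP(t)^2 per map
  denom <- sum(gfp2)
  best <- NULL
  with_seed(config$seed, {
    for (r in seq_len(config$n_restarts)) {
      init <- sample.int(N, K)
      run <- kmeans_run(X, Xn, gfp2, denom, K, init, config)
      if (is.null(best) || run$gev > best$gev) best <- run
    }
  })
  tmpl <- template_set(best$templates, provenance = "kmeans",
                       gev = best$gev_per_map)
  structure(list(templates = tmpl, labels = best$labels, gev = best$gev,
                 gev_trace = best$gev_trace, K = K),
            class = "microstate_fit")
}

kmeans_run <- function(X, Xn, gfp2, denom, K, init, config) {
  A <- Xn[, init, drop = FALSE]
  gev_prev <- -Inf
  gev_trace <- numeric(0)
  labels <- rep(0L, ncol(X))
  for (it in seq_len(config$max_iter)) {
    r_abs <- abs(crossprod(A, Xn))            # K x N
    labels_new <- max.col(t(r_abs), ties.method = "first")
    # refill empty clusters from the worst-fit map
    fit <- r_abs[cbind(labels_new, seq_len(ncol(X)))]
    for (k in seq_len(K)) {
      if (!any(labels_new == k)) {
        worst <- which.min(fit)
        labels_new[worst] <- k
        fit[worst] <- 1
      }
    }
    for (k in seq_len(K)) {
      idx <- which(labels_new == k)
      S <- X[, idx, drop = FALSE]
      ev <- eigen(tcrossprod(S), symmetric = TRUE)
      v <- ev$vectors[, 1L]
      v <- v * sign(v[which.max(abs(v))])      # canonical sign
      A[, k] <- v / sqrt(sum(v^2))
    }
    r_abs <- abs(crossprod(A, Xn))
    fit <- r_abs[cbind(labels_new, seq_len(ncol(X)))]
    gev <- sum(gfp2 * fit^2) / denom
    gev_trace <- c(gev_trace, gev)
    labels <- labels_new
    if (gev - gev_prev < config$tol) break
    gev_prev <- gev
  }
  r_abs <- abs(crossprod(A, Xn))
  fit <- r_abs[cbind(labels, seq_len(ncol(X)))]
  gev_per_map <- vapply(seq_len(K), function(k) {
    sum((gfp2 * fit^2)[labels == k]) / denom
  }, numeric(1))
  list(templates = A, labels = labels, gev = sum(gev_per_map),
       gev_per_map = gev_per_map, gev_trace = gev_trace)
}

#' Group-level clustering of subject templates
#'
#' Pools the template maps of all subjects and applies the same
#' polarity-invariant modified k-means, mirroring the two-stage
#' (within-subject, then across-subject) procedure.  `K` may be fixed or
#' chosen by the seven-criterion meta-criterion over `k_range`.
#'
#' @param subject_template_sets list of [template_set()]s (>= 2 subjects).
#' @param K fixed number of group clusters, or `NULL` to select via
#'   [choose_k()].
#' @param k_range candidate K values when `K` is `NULL`.
#' @param config a [kmeans_config()].
#' @return a `microstate_fit` (plus `$validity` when K was selected).
#' @export
group_cluster <- function(subject_template_sets, K = NULL, k_range = 2:12,
                          config = kmeans_config()) {
  if (length(subject_template_sets) < 2L) stopf("need at least 2 subjects")
  pooled <- do.call(cbind, lapply(subject_template_sets, function(ts) {
    if (inherits(ts, "template_set")) ts$maps else as.matrix(ts)
  }))
  if (is.null(K)) {
    sel <- choose_k(pooled, k_range = k_range, config = config)
    fit <- sel$fits[[as.character(sel$meta_k)]]
    fit$validity <- sel
    fit$templates$provenance <- "group"
    return(fit)
  }
  fit <- modified_kmeans(pooled, K, config)
  fit$templates$provenance <- "group"
  fit
}
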