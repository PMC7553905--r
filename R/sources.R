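#' Build a distributed linear inverse operator
#'
#' Generic weighted-minimum-norm inverse
#' `G = W L' (L W L' + lambda C)^-1` with identity noise covariance C and a
#' selectable source weighting W: `"depth"` (default; per-source-point
#' column-norm normalization, compensating the bias toward superficial
#' sources), `"smooth"` (depth weighting combined with nearest-neighbour
#' spatial smoothness, a local-autoregressive-style surrogate) or `"none"`.
#' The default regularization follows an SNR rule,
#' `lambda = trace(L W L') / (n_channels * snr^2)`.
#'
#' @param leadfield a `leadfield` (see [toy_leadfield()]) or list with
#'   `gain` (channels x 3 n_points) and `source_positions`.
#' @param lambda nonnegative regularization, or `NULL` for the SNR rule.
#' @param snr assumed amplitude SNR for the default lambda rule.
#' @param weighting `"depth"`, `"smooth"` or `"none"`.
#' @return an `inverse_operator`: `operator` (3 n_points x channels),
#'   `n_points`, `lambda`, `source_positions`.
#' @export
build_inverse_operator <- function(leadfield, lambda = NULL, snr = 3,
                                   weighting = c("depth", "smooth", "none")) {
  weighting <- match.arg(weighting)
  L <- leadfield$gain
  nc <- nrow(L)
  np <- ncol(L) / 3L
  w <- rep(1, ncol(L))
  if (weighting != "none") {
    pt <- rep(seq_len(np), each = 3L)
    cn2 <- colSums(L^2)
    pn2 <- tapply(cn2, pt, sum)       # squared Frobenius norm per point
    pn2[pn2 == 0] <- Inf              # degenerate points get zero weight
    w <- 1 / sqrt(pn2)[pt]
  }
  W <- w
  LW <- sweep(L, 2L, W, "*")          # L W (diagonal W)
  M <- LW %*% t(L)                    # L W L'
  if (weighting == "smooth") {
    # neighbourhood smoothing of the weighted gain: average each point's
    # columns with its 6 nearest neighbours before forming the gram matrix
    pos <- leadfield$source_positions
    nn <- apply(as.matrix(stats::dist(pos)), 1L, function(d) {
      order(d)[seq_len(min(7L, length(d)))]
    })
    A <- matrix(0, np, np)
    for (j in seq_len(np)) A[nn[, j], j] <- 1 / nrow(nn)
    Sm <- kronecker(A, diag(3))
    LW <- LW %*% Sm
    M <- LW %*% t(L)
    M <- (M + t(M)) / 2
  }
  if (is.null(lambda)) lambda <- sum(diag(M)) / (nc * snr^2)
  if (lambda < 0) stopf("lambda must be nonnegative")
  Mi <- tryCatch(solve(M + diag(lambda, nc)),
                 error = function(e) stopf("singular system; increase lambda"))
  structure(list(operator = t(LW) %*% Mi, n_points = np, lambda = lambda,
                 source_positions = leadfield$source_positions),
            class = "inverse_operator")
}

#' Apply an inverse operator to scalp data
#'
#' Maps average-referenced scalp data to per-point current-density
#' magnitudes (the polarity-free norm of the 3-D moment vector), consistent
#' with polarity-ignored microstates.  Adding a common offset to all
#' channels does not change the estimate because the operator was built
#' from average-referenced gains.
#'
#' @param inv an `inverse_operator`.
#' @param x channels x time matrix or [eeg_recording()].
#' @return a `source_estimate`: `magnitude` (n_points x time), `moments`
#'   (3 n_points x time), `source_positions`.
#' @export
apply_inverse <- function(inv, x) {
  m <- if (inherits(x, "eeg_recording")) x$data else as.matrix(x)
  m <- center_cols(m)
  mom <- inv$operator %*% m
  idx <- matrix(seq_len(3L * inv$n_points), nrow = 3L)
  mag <- sqrt(mom[idx[1L, ], , drop = FALSE]^2 +
                mom[idx[2L, ], , drop = FALSE]^2 +
                mom[idx[3L, ], , drop = FALSE]^2)
  structure(list(magnitude = mag, moments = mom,
                 source_positions = inv$source_positions),
            class = "source_estimate")
}

#' Standardize source magnitudes across time
#'
#' Divides each solution point's magnitude time course by its own temporal
#' standard deviation, removing per-point activation biases; points with
#' zero SD are set to 0 and flagged.  The standardized estimate is
#' invariant to rescaling the whole recording.
#'
#' @param est a `source_estimate` with at least 2 time points.
#' @return the estimate with standardized `magnitude` and a logical
#'   `degenerate` flag per point (`moments` are dropped, standardization is
#'   magnitude-level).
#' @export
standardize_sources <- function(est) {
  stopifnot(inherits(est, "source_estimate"))
  if (ncol(est$magnitude) < 2L) stopf("need at least 2 time points")
  sds <- apply(est$magnitude, 1L, stats::sd)
  degenerate <- sds == 0
  sds[degenerate] <- Inf
  est$magnitude <- est$magnitude / sds
  est$moments <- NULL
  est$degenerate <- degenerate
  est
}

#' Mean source map of one microstate
#'
#' Per-point mean (standardized) magnitude over the time points labelled
#' with one map.
#'
#' @param est a `source_estimate` (typically standardized).
#' @param labels label vector aligned to the estimate's time axis.
#' @param map_id which map.
#' @return numeric vector, one value per solution point (all `NA` if the
#'   map never occurs).
#' @export
microstate_source_map <- function(est, labels, map_id) {
  stopifnot(inherits(est, "source_estimate"))
  if (length(labels) != ncol(est$magnitude)) {
    stopf("labels not aligned to the source estimate")
  }
  sel <- which(!is.na(labels) & labels == map_id)
  if (!length(sel)) return(rep(NA_real_, nrow(est$magnitude)))
  rowMeans(est$magnitude[, sel, drop = FALSE])
}

#' Percentile threshold mask
#'
#' Retains the solution points strictly above the q-th percentile of the
#' across-subject mean map (type-7 quantile).  With all values equal the
#' mask is empty — the strictly-above tie convention.
#'
#' @param group_mean_map numeric vector (mean map across subjects).
#' @param q percentile in (0, 100), default 95.
#' @return logical mask over solution points.
#' @export
percentile_threshold <- function(group_mean_map, q = 95) {
  if (q <= 0 || q >= 100) stopf("q must be in (0, 100)")
  thr <- stats::quantile(group_mean_map, q / 100, na.rm = TRUE, names = FALSE)
  !is.na(group_mean_map) & group_mean_map > thr
}

#' Voxelwise paired randomization between two source-map sets
#'
#' Applies [paired_randomization_test()] at every retained solution point
#' to the per-subject mean source maps of two microstates (or conditions);
#' significance at `p < alpha`, uncorrected, on purpose restricted to the
#' high-activation mask from [percentile_threshold()].
#'
#' @param maps_a,maps_b subjects x n_points matrices of per-subject source
#'   maps.
#' @param mask logical mask of retained points.
#' @param alpha uncorrected significance level (default 0.005).
#' @param n_perm,seed passed to [paired_randomization_test()].
#' @return data.frame `point, p, significant` (one row per retained point).
#' @export
voxelwise_randomization <- function(maps_a, maps_b, mask, alpha = 0.005,
                                    n_perm = 5000L, seed = 1L) {
  stopifnot(all(dim(maps_a) == dim(maps_b)),
            length(mask) == ncol(maps_a))
  pts <- which(mask)
  res <- lapply(seq_along(pts), function(i) {
    j <- pts[i]
    tst <- paired_randomization_test(maps_a[, j], maps_b[, j],
                                     n_perm = n_perm,
                                     seed = derive_seed(seed, j, 0L))
    data.frame(point = j, p = tst$p, statistic = tst$statistic)
  })
  out <- do.call(rbind, res) %||%
    data.frame(point = integer(0), p = numeric(0), statistic = numeric(0))
  out$significant <- out$p < alpha
  out
}
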