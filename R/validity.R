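#' Polarity-invariant pairwise dissimilarity between maps
#'
#' `d(a, b) = sqrt(2 * (1 - |r(a, b)|))` with `r` the spatial (Pearson)
#' correlation, so identical and sign-flipped maps are at distance 0 and
#' orthogonal maps at `sqrt(2)`.  This is the metric all seven validity
#' criteria operate on.
#'
#' @param maps numeric channels x N matrix.
#' @return symmetric N x N matrix with zero diagonal.
#' @export
pairwise_dissimilarity <- function(maps) {
  maps <- as.matrix(maps)
  if (ncol(maps) < 2L) stopf("need at least 2 maps")
  if (any(colSums(center_cols(maps)^2) == 0)) {
    zero_variance_error("zero-variance map in dissimilarity computation")
  }
  r <- colwise_correlation(maps, maps)
  d2 <- 2 * (1 - pmin(abs(r), 1))
  d <- sqrt(pmax(d2, 0))
  diag(d) <- 0
  d
}

# Goodman-Kruskal Gamma via sorted between-cluster distances:
# s+ = #{(w, b): w < b}, s- = #{w > b}; ties count for neither.
gk_gamma <- function(w, b) {
  if (!length(w) || !length(b)) return(NA_real_)
  bs <- sort(b)
  le <- findInterval(w, bs)                      # b <= w
  lt <- findInterval(w, bs, left.open = TRUE)    # b <  w
  splus <- sum(length(b) - le)
  sminus <- sum(lt)
  if (splus + sminus == 0) return(NA_real_)
  (splus - sminus) / (splus + sminus)
}

mean_silhouette <- function(D, labels) {
  n <- length(labels)
  ks <- sort(unique(labels))
  sizes <- tabulate(match(labels, ks))
  ind <- outer(labels, ks, "==") + 0          # n x K membership
  sums <- D %*% ind                           # n x K: sum dist to each cluster
  s <- numeric(n)
  for (i in seq_len(n)) {
    k <- match(labels[i], ks)
    if (sizes[k] == 1L) { s[i] <- 0; next }
    a <- sums[i, k] / (sizes[k] - 1L)
    bvals <- sums[i, -k, drop = TRUE] / sizes[-k]
    b <- min(bvals)
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Seven cluster-validity criteria over a range of K
#'
#' Computes, for each fitted segmentation, the Goodman-Kruskal Gamma, mean
#' silhouette, Davies-Bouldin index, point-biserial correlation, Dunn index,
#' Krzanowski-Lai index and the predictive-residual cross-validation
#' criterion, all on the polarity-invariant dissimilarity of
#' [pairwise_dissimilarity()].  Variant choices (the classical definitions;
#' centroid = cluster template, Dunn = single-linkage separation over
#' complete diameter, Krzanowski-Lai W = summed squared dissimilarities to
#' the template) are fixed and documented here because the criteria exist
#' under many variants in the literature.
#'
#' @param peak_maps channels x N matrix the segmentations were fitted on.
#' @param fits named list of `microstate_fit`s, names = K (a contiguous K
#'   grid makes Krzanowski-Lai available in the interior).
#' @return a `validity_profile` data.frame, one row per K, one column per
#'   criterion (NA where a criterion is undefined at that K).
#' @export
compute_validity_criteria <- function(peak_maps, fits) {
  X <- center_cols(as.matrix(peak_maps))
  C <- nrow(X)
  N <- ncol(X)
  D <- pairwise_dissimilarity(X)
  ut <- upper.tri(D)
  ks <- as.integer(names(fits))
  ord <- order(ks)
  ks <- ks[ord]; fits <- fits[ord]
  res <- data.frame(K = ks, gamma = NA_real_, silhouette = NA_real_,
                    davies_bouldin = NA_real_, point_biserial = NA_real_,
                    dunn = NA_real_, krzanowski_lai = NA_real_,
                    cross_validation = NA_real_)
  W <- setNames(rep(NA_real_, length(ks)), ks)
  for (i in seq_along(ks)) {
    fit <- fits[[i]]
    labels <- fit$labels
    tmpl <- fit$templates$maps
    same <- outer(labels, labels, "==")
    w <- D[ut & same]; b <- D[ut & !same]
    res$gamma[i] <- gk_gamma(w, b)
    res$silhouette[i] <- mean_silhouette(D, labels)
    res$point_biserial[i] <- if (length(w) && length(b) &&
                                 stats::sd(D[ut]) > 0) {
      stats::cor(D[ut], as.numeric(!same[ut]))
    } else NA_real_
    # distances of every map to every template, polarity-invariant
    dt <- sqrt(pmax(2 * (1 - abs(colwise_correlation(tmpl, X))), 0))
    dpt <- dt[cbind(labels, seq_len(N))]
    # Davies-Bouldin with centroid = template
    kk <- ks[i]
    S <- vapply(seq_len(kk), function(k) mean(dpt[labels == k]), numeric(1))
    M <- pairwise_dissimilarity(tmpl)
    if (kk >= 2L) {
      ratio <- (outer(S, S, "+")) / M
      diag(ratio) <- -Inf
      res$davies_bouldin[i] <- mean(apply(ratio, 1L, max))
      res$dunn[i] <- {
        between_min <- min(D[!same], na.rm = TRUE)
        diam_max <- max(D[same & ut], 0, na.rm = TRUE)
        if (diam_max == 0) Inf else between_min / diam_max
      }
    }
    W[i] <- sum(dpt^2)
    # predictive-residual cross-validation criterion (minimize)
    if (C - kk - 1L > 0L) {
      Xn <- unitize_cols(X)
      proj <- abs(crossprod(tmpl, Xn))[cbind(labels, seq_len(N))]
      resid <- colSums(X^2) * (1 - proj^2)
      sigma2 <- sum(resid) / (N * (C - 1L))
      res$cross_validation[i] <- sigma2 * ((C - 1L) / (C - kk - 1L))^2
    }
  }
  # Krzanowski-Lai over the K grid: DIFF(K) = (K-1)^(2/p) W_{K-1} - K^(2/p) W_K
  p <- C
  for (i in seq_along(ks)) {
    km1 <- match(ks[i] - 1L, ks); kp1 <- match(ks[i] + 1L, ks)
    if (!is.na(km1) && !is.na(kp1)) {
      diff_k <- (ks[i] - 1L)^(2 / p) * W[km1] - ks[i]^(2 / p) * W[i]
      diff_k1 <- ks[i]^(2 / p) * W[i] - (ks[i] + 1L)^(2 / p) * W[kp1]
      res$krzanowski_lai[i] <- if (diff_k1 == 0) NA_real_ else
        abs(diff_k) / abs(diff_k1)
    }
  }
  attr(res, "W") <- W
  class(res) <- c("validity_profile", "data.frame")
  res
}

#' Per-criterion optimal K
#'
#' Gamma, silhouette, point-biserial, Dunn and Krzanowski-Lai are
#' maximized; Davies-Bouldin and cross-validation are minimized.  Ties
#' break toward smaller K; criteria undefined everywhere are dropped.
#'
#' @param profile a `validity_profile` from [compute_validity_criteria()].
#' @return named integer vector of per-criterion optimal K values.
#' @export
select_optimal_k <- function(profile) {
  maximize <- c(gamma = TRUE, silhouette = TRUE, davies_bouldin = FALSE,
                point_biserial = TRUE, dunn = TRUE, krzanowski_lai = TRUE,
                cross_validation = FALSE)
  opts <- integer(0)
  for (crit in names(maximize)) {
    v <- profile[[crit]]
    if (all(is.na(v))) next
    v <- if (maximize[[crit]]) v else -v
    v[is.na(v)] <- -Inf
    opts[crit] <- profile$K[which.max(v)]   # which.max: first max = smaller K
  }
  if (!length(opts)) stopf("no criterion yielded an optimum")
  opts
}

#' Meta-criterion: median of the per-criterion optima
#'
#' For an even number of available optima the lower middle value is taken,
#' a conservative rule that always returns an actually-attained K.
#'
#' @param optima integer vector of per-criterion optimal K values.
#' @return integer K*.
#' @export
meta_criterion <- function(optima) {
  optima <- optima[!is.na(optima)]
  if (!length(optima)) stopf("empty optimum list")
  s <- sort(optima)
  as.integer(s[floor((length(s) + 1) / 2)])
}

#' Choose the number of microstates
#'
#' Runs [modified_kmeans()] for every K in `k_range`, evaluates the seven
#' validity criteria and returns their optima and the meta-criterion K.
#'
#' @param peak_maps channels x N matrix (maps at GFP peaks, or pooled
#'   subject templates for the group stage).
#' @param k_range candidate K values.
#' @param config a [kmeans_config()].
#' @return list with `profile`, `optima`, `meta_k` and `fits` (named by K).
#' @export
choose_k <- function(peak_maps, k_range = 2:12, config = kmeans_config()) {
  N <- ncol(as.matrix(peak_maps))
  k_range <- k_range[k_range >= 2L & k_range <= N]
  if (!length(k_range)) stopf("no feasible K in range")
  fits <- lapply(k_range, function(k) modified_kmeans(peak_maps, k, config))
  names(fits) <- k_range
  profile <- compute_validity_criteria(peak_maps, fits)
  optima <- select_optimal_k(profile)
  list(profile = profile, optima = optima,
       meta_k = meta_criterion(optima), fits = fits)
}
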