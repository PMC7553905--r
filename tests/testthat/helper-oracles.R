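# Independent brute-force reference implementations used as oracles.
# Everything here is deliberately written as plain loops over the defining
# formulas, never calling the package's vectorized code paths.

oracle_gfp <- function(mat) {
  vapply(seq_len(ncol(mat)), function(t) {
    v <- mat[, t]
    v <- v - mean(v)
    sqrt(sum(v^2) / length(v))
  }, numeric(1))
}

oracle_pearson <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

oracle_dissim <- function(maps) {
  n <- ncol(maps)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) {
      d[i, j] <- sqrt(2 * (1 - abs(oracle_pearson(maps[, i], maps[, j]))))
    }
  }
  d
}

oracle_gev <- function(mat, templates, labels) {
  K <- ncol(templates)
  gfp <- oracle_gfp(mat)
  denom <- sum(gfp^2)
  gev <- numeric(K)
  for (t in seq_len(ncol(mat))) {
    if (is.na(labels[t])) next
    r <- oracle_pearson(mat[, t], templates[, labels[t]])
    gev[labels[t]] <- gev[labels[t]] + (gfp[t] * r)^2
  }
  gev / denom
}

# Run-length statistics cutting at epoch boundaries (0-based half-open).
oracle_segment_stats <- function(labels, sfreq, K, epochs) {
  runs <- list()
  for (e in seq_len(nrow(epochs))) {
    idx <- (epochs[e, 1] + 1L):epochs[e, 2]
    cur <- NA; len <- 0L
    for (i in idx) {
      li <- labels[i]
      if (!is.na(cur) && !is.na(li) && li == cur) {
        len <- len + 1L
      } else {
        if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
        cur <- li; len <- 1L
      }
    }
    if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
  }
  runs <- do.call(rbind, runs)
  n_labeled <- sum(!is.na(labels))
  out <- data.frame(map = seq_len(K), mean_duration_ms = NA_real_,
                    occurrence_hz = 0, coverage = 0)
  for (k in seq_len(K)) {
    rk <- runs[runs[, 1] == k, 2]
    if (length(rk)) {
      out$mean_duration_ms[k] <- mean(rk) * 1000 / sfreq
      out$occurrence_hz[k] <- length(rk) / (n_labeled / sfreq)
      out$coverage[k] <- sum(rk) / n_labeled
    }
  }
  out
}

# ---- validity criteria, defined directly on a dissimilarity matrix --------

oracle_gamma <- function(D, labels) {
  n <- length(labels)
  w <- c(); b <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) w <- c(w, D[i, j]) else b <- c(b, D[i, j])
  }
  sp <- 0; sm <- 0
  for (wi in w) for (bj in b) {
    if (wi < bj) sp <- sp + 1
    if (wi > bj) sm <- sm + 1
  }
  if (sp + sm == 0) return(NA_real_)
  (sp - sm) / (sp + sm)
}

oracle_silhouette <- function(D, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- Inf
    for (k in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(D[i, labels == k]))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_template_dist <- function(map, tmpl) {
  sqrt(2 * (1 - abs(oracle_pearson(map, tmpl))))
}

oracle_db <- function(maps, templates, labels) {
  K <- ncol(templates)
  S <- numeric(K)
  for (k in seq_len(K)) {
    idx <- which(labels == k)
    S[k] <- mean(vapply(idx, function(i) {
      oracle_template_dist(maps[, i], templates[, k])
    }, numeric(1)))
  }
  tot <- 0
  for (k in seq_len(K)) {
    best <- -Inf
    for (j in seq_len(K)) {
      if (j == k) next
      m <- oracle_template_dist(templates[, j], templates[, k])
      best <- max(best, (S[k] + S[j]) / m)
    }
    tot <- tot + best
  }
  tot / K
}

oracle_pb <- function(D, labels) {
  n <- length(labels)
  d <- c(); ind <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- c(d, D[i, j])
    ind <- c(ind, as.numeric(labels[i] != labels[j]))
  }
  stats::cor(d, ind)
}

oracle_dunn <- function(D, labels) {
  n <- length(labels)
  sep <- Inf; diam <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (labels[i] == labels[j]) diam <- max(diam, D[i, j])
    else sep <- min(sep, D[i, j])
  }
  if (diam == 0) Inf else sep / diam
}

oracle_W <- function(maps, templates, labels) {
  tot <- 0
  for (i in seq_along(labels)) {
    tot <- tot + oracle_template_dist(maps[, i], templates[, labels[i]])^2
  }
  tot
}

oracle_cv <- function(maps, templates, labels) {
  C <- nrow(maps)
  K <- ncol(templates)
  tot <- 0
  for (i in seq_along(labels)) {
    x <- maps[, i] - mean(maps[, i])
    a <- templates[, labels[i]] - mean(templates[, labels[i]])
    a <- a / sqrt(sum(a^2))
    tot <- tot + sum(x^2) - sum(a * x)^2
  }
  sigma2 <- tot / (length(labels) * (C - 1))
  sigma2 * ((C - 1) / (C - K - 1))^2
}

# Exhaustive sign-flip p by explicit enumeration over bit patterns.
oracle_signflip_p <- function(a, b) {
  d <- a - b
  n <- length(d)
  obs <- mean(d)
  cnt <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0, 1, -1)
    if (abs(mean(signs * d)) >= abs(obs)) cnt <- cnt + 1
  }
  cnt / 2^n
}

# Welch-style FFT band-power fraction used to sanity-check carriers.
fft_band_fraction <- function(x, sfreq, band) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_len(n) - 1) * sfreq / n
  half <- fr <= sfreq / 2
  sum(sp[half & fr >= band[1] & fr <= band[2]]) / sum(sp[half & fr >= 0.5])
}
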