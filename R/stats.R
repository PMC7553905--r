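#' Two-way fully-within-subject ANOVA (2 conditions x K levels)
#'
#' Direct sums-of-squares decomposition for a complete balanced
#' subject x condition x level design: main effects of condition and level
#' and their interaction, each tested against its own
#' subject-by-effect error term.  The Greenhouse-Geisser sphericity
#' correction epsilon is estimated from the covariance matrix of the
#' orthonormalized within-subject effect scores and applied
#' unconditionally (no sphericity pre-test); both uncorrected and
#' GG-corrected p values are reported, plus partial eta squared
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param y numeric array `subjects x 2 x K` (use
#'   [metrics_to_array()] to build one from a tidy metrics table).
#' @return data.frame with one row per effect (`condition`, `level`,
#'   `condition:level`): F, df, uncorrected p, epsilon, GG-corrected p,
#'   partial eta squared.
#' @export
rm_anova_2xk <- function(y) {
  stopifnot(is.array(y), length(dim(y)) == 3L, dim(y)[2L] == 2L)
  if (anyNA(y)) stopf("missing cells in the design")
  S <- dim(y)[1L]; K <- dim(y)[3L]
  if (S < 3L) stopf("need at least 3 subjects")
  mu <- mean(y)
  m_s <- apply(y, 1L, mean)
  m_c <- apply(y, 2L, mean)
  m_k <- apply(y, 3L, mean)
  m_sc <- apply(y, c(1L, 2L), mean)
  m_sk <- apply(y, c(1L, 3L), mean)
  m_ck <- apply(y, c(2L, 3L), mean)
  ss_c <- S * K * sum((m_c - mu)^2)
  ss_k <- S * 2 * sum((m_k - mu)^2)
  ss_ck <- S * sum((m_ck - outer(m_c, rep(1, K)) -
                      outer(rep(1, 2), m_k) + mu)^2)
  err_c <- K * sum((m_sc - outer(m_s, rep(1, 2)) -
                      outer(rep(1, S), m_c) + mu)^2)
  err_k <- 2 * sum((m_sk - outer(m_s, rep(1, K)) -
                      outer(rep(1, S), m_k) + mu)^2)
  full <- y
  for (s in seq_len(S)) for (ci in 1:2) for (k in seq_len(K)) {
    full[s, ci, k] <- y[s, ci, k] - m_sc[s, ci] - m_sk[s, k] - m_ck[ci, k] +
      m_s[s] + m_c[ci] + m_k[k] - mu
  }
  err_ck <- sum(full^2)

  gg_eps <- function(scores) {
    # scores: subjects x df matrix of orthonormal within-subject contrasts
    V <- stats::cov(scores)
    d <- ncol(scores)
    sum(diag(V))^2 / (d * sum(V^2))
  }
  helmert_on <- function(n) {
    h <- stats::contr.helmert(n)
    qr.Q(qr(h))
  }
  ck <- helmert_on(K)
  # level effect: scores from condition-averaged data
  z_k <- apply(y, c(1L, 3L), mean) %*% ck
  # interaction: scores from the condition difference
  z_ck <- (y[, 1L, ] - y[, 2L, ]) %*% ck
  effects <- data.frame(
    effect = c("condition", "level", "condition:level"),
    ss = c(ss_c, ss_k, ss_ck),
    ss_error = c(err_c, err_k, err_ck),
    df1 = c(1, K - 1, K - 1),
    df2 = c(S - 1, (S - 1) * (K - 1), (S - 1) * (K - 1)),
    epsilon = c(1, gg_eps(z_k), gg_eps(z_ck)))
  if (any(effects$ss_error == 0 & effects$ss > 0)) {
    stopf("zero error variance: degenerate design")
  }
  effects$F <- ifelse(effects$ss == 0, 0,
                      (effects$ss / effects$df1) /
                        (effects$ss_error / effects$df2))
  effects$epsilon[!is.finite(effects$epsilon)] <- 1
  effects$p <- stats::pf(effects$F, effects$df1, effects$df2,
                         lower.tail = FALSE)
  effects$p_gg <- stats::pf(effects$F, effects$df1 * effects$epsilon,
                            effects$df2 * effects$epsilon,
                            lower.tail = FALSE)
  effects$partial_eta_sq <- ifelse(effects$ss == 0, 0,
                                   effects$ss / (effects$ss + effects$ss_error))
  effects[, c("effect", "F", "df1", "df2", "p", "epsilon", "p_gg",
              "partial_eta_sq")]
}

#' Reshape a tidy metrics table to a subjects x condition x map array
#'
#' @param metrics data.frame as from [microstate_metrics()] (rows for every
#'   subject, condition and map).
#' @param value which metric column to use.
#' @param conditions optional explicit condition order.
#' @return numeric array `subjects x 2 x K`.
#' @export
metrics_to_array <- function(metrics, value = "gev", conditions = NULL) {
  if (is.null(conditions)) conditions <- unique(metrics$condition)
  subs <- unique(metrics$subject)
  maps <- sort(unique(metrics$map))
  y <- array(NA_real_, c(length(subs), length(conditions), length(maps)),
             dimnames = list(subs, conditions, maps))
  for (i in seq_len(nrow(metrics))) {
    y[match(metrics$subject[i], subs),
      match(metrics$condition[i], conditions),
      match(metrics$map[i], maps)] <- metrics[[value]][i]
  }
  y
}

#' Bonferroni correction
#'
#' `p_corr = min(1, m * p)`; thin wrapper kept for a uniform interface.
#'
#' @param p vector of uncorrected p values.
#' @param m number of comparisons (defaults to `length(p)`).
#' @return corrected p values.
#' @export
bonferroni_posthoc <- function(p, m = length(p)) {
  if (m < 1) stopf("need m >= 1")
  pmin(1, m * p)
}

#' Per-level condition post-hocs
#'
#' Paired t-tests of condition 1 vs condition 2 at each level (map), with
#' Bonferroni correction over the K comparisons — the usual follow-up to a
#' significant condition-by-map interaction.
#'
#' @param y array `subjects x 2 x K` (see [metrics_to_array()]).
#' @return data.frame `level, mean_diff, t, df, p, p_bonf, direction`.
#' @export
posthoc_condition_by_level <- function(y) {
  K <- dim(y)[3L]
  out <- lapply(seq_len(K), function(k) {
    d <- y[, 1L, k] - y[, 2L, k]
    tt <- stats::t.test(d)
    data.frame(level = k, mean_diff = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, out)
  out$p_bonf <- bonferroni_posthoc(out$p, K)
  out$direction <- sign(out$mean_diff)
  out
}

#' Paired sign-flip randomization test
#'
#' Tests the mean paired difference `mean(a - b)` against the null of
#' exchangeable signs: all `2^n` sign patterns are enumerated when
#' `2^n <= max_exhaustive`, otherwise `n_perm` seeded Monte-Carlo draws are
#' used.  Two-tailed via the absolute statistic; Monte-Carlo p uses the
#' add-one estimator `(count + 1) / (N + 1)` so p is never 0, exhaustive p
#' is the exact proportion.
#'
#' @param a,b equal-length paired samples (n >= 2).
#' @param n_perm Monte-Carlo permutation count.
#' @param seed RNG seed (Monte-Carlo only).
#' @param max_exhaustive enumeration budget (default 4096 patterns).
#' @return list: `statistic`, `p`, `n_perm` (patterns used), `exhaustive`,
#'   `degenerate` (all differences zero), `seed`.
#' @export
paired_randomization_test <- function(a, b, n_perm = 5000L, seed = 1L,
                                      max_exhaustive = 4096L) {
  if (length(a) != length(b)) stopf("paired samples differ in length")
  n <- length(a)
  if (n < 2L) stopf("need n >= 2 pairs")
  d <- a - b
  obs <- mean(d)
  if (all(d == 0)) {
    return(list(statistic = 0, p = 1, n_perm = 0L, exhaustive = TRUE,
                degenerate = TRUE, seed = seed))
  }
  if (2^n <= max_exhaustive) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    # same summation order as `obs` so exact ties (identity and global
    # flip) compare bit-equal
    tstar <- apply(signs, 1L, function(s) mean(s * d))
    p <- mean(abs(tstar) >= abs(obs))
    return(list(statistic = obs, p = p, n_perm = nrow(signs),
                exhaustive = TRUE, degenerate = FALSE, seed = seed))
  }
  count <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    nrow = n_perm)
    tstar <- as.vector(signs %*% d) / n
    sum(abs(tstar) >= abs(obs))
  })
  list(statistic = obs, p = (count + 1) / (n_perm + 1), n_perm = n_perm,
       exhaustive = FALSE, degenerate = FALSE, seed = seed)
}
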