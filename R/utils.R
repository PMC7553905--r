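# Internal helpers shared across modules.

# Run `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so seeded package functions never disturb
# the session RNG.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Column-wise centering (average reference of one map per column).
center_cols <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# Centre + scale columns to unit L2 norm; zero-variance columns become NaN
# unless `zero_ok`, in which case they are left as zeros.
unitize_cols <- function(x, zero_ok = FALSE) {
  x <- center_cols(x)
  nrm <- sqrt(colSums(x^2))
  if (zero_ok) nrm[nrm == 0] <- Inf
  sweep(x, 2L, nrm, "/")
}

# Pearson correlation between every column of `a` (channels x K) and every
# column of `b` (channels x N): K x N matrix.  Maps are centred across
# channels first, so for average-referenced maps this is the cosine.
colwise_correlation <- function(a, b) {
  crossprod(unitize_cols(a), unitize_cols(b))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

# Legendre polynomials P_n(x) and derivatives P_n'(x) for n = 1..nmax,
# evaluated by the three-term recurrence.  Returns list of two
# length(x) x nmax matrices.  Used by the spherical-spline interpolator and
# the single-sphere lead field.
legendre_table <- function(x, nmax) {
  p  <- matrix(0, length(x), nmax)
  dp <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))   # P_0
  p0  <- x                   # P_1
  dpm1 <- rep(0, length(x))
  dp0  <- rep(1, length(x))
  p[, 1] <- p0
  dp[, 1] <- dp0
  if (nmax >= 2) {
    for (n in 2:nmax) {
      pn  <- ((2 * n - 1) * x * p0 - (n - 1) * pm1) / n
      dpn <- dpm1 + (2 * n - 1) * p0
      p[, n] <- pn
      dp[, n] <- dpn
      pm1 <- p0; p0 <- pn
      dpm1 <- dp0; dp0 <- dpn
    }
  }
  list(p = p, dp = dp)
}

# Evenly spread unit-sphere points (Fibonacci lattice); default electrode
# montage for synthetic recordings.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}
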