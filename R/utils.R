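# Internal helpers shared across the package.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded package functions do not perturb user sessions.
eval_with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had_seed) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a stream-specific sub-seed from a master seed; stays within the
# 32-bit signed integer range R requires of set.seed().
derive_seed <- function(seed, index) {
  as.integer((abs(as.numeric(seed)) %% 1e5) * 20011 + index * 7919) %% 2147483647L
}

# Draw n vectors from MVN(mean, sigma) for a symmetric PSD sigma, via
# eigendecomposition so that singular (including all-zero) covariances are
# handled exactly: degenerate directions contribute no noise.
rmvnorm_psd <- function(n, mean, sigma, tol = 1e-8) {
  d <- length(mean)
  sigma <- as.matrix(sigma)
  stopifnot(nrow(sigma) == d, ncol(sigma) == d)
  if (max(abs(sigma - t(sigma))) > tol * max(1, max(abs(sigma)))) {
    stop("covariance matrix is not symmetric")
  }
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  if (any(ev$values < -tol * max(1, abs(ev$values[1L])))) {
    stop("covariance matrix is not positive semi-definite")
  }
  lam <- pmax(ev$values, 0)
  z <- matrix(stats::rnorm(n * d), nrow = n, ncol = d)
  x <- z %*% (t(ev$vectors) * sqrt(lam))
  sweep(x, 2L, mean, "+")
}

# Truncated-normal draws by inverse-CDF; sd = 0 returns the (clamped) mean.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  stopifnot(lo < hi, sd >= 0)
  if (sd == 0) {
    return(rep(min(max(mean, lo), hi), n))
  }
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
}

# Check a square matrix is symmetric PSD (used by config validation).
is_psd <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) return(FALSE)
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) return(FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  all(ev >= -tol * max(1, abs(ev[1L])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
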