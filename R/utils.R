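# Internal helpers shared across modules.

# Evaluate with the global RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Legendre polynomial basis P_0..P_order evaluated on n equally spaced points
# mapped to [-1, 1]; columns are the polynomials in increasing degree.
legendre_basis <- function(n, order) {
  stopifnot(n >= 1L, order >= 0L)
  x <- if (n == 1L) 0 else seq(-1, 1, length.out = n)
  P <- matrix(0, nrow = n, ncol = order + 1L)
  P[, 1L] <- 1
  if (order >= 1L) P[, 2L] <- x
  if (order >= 2L) {
    for (k in 2L:order) {
      # (k) P_k = (2k-1) x P_{k-1} - (k-1) P_{k-2}
      P[, k + 1L] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1L]) / k
    }
  }
  P
}

# Numerical matrix rank by singular values relative to the largest.
mat_rank <- function(A, tol = 1e-8) {
  if (length(A) == 0L) return(0L)
  d <- svd(A, nu = 0L, nv = 0L)$d
  if (!length(d) || d[1L] == 0) return(0L)
  sum(d > tol * d[1L])
}

# Minimum-norm least squares via SVD pseudoinverse; returns list(coef, rank).
lstsq_minnorm <- function(X, Y, tol = 1e-8) {
  s <- svd(X)
  keep <- s$d > tol * s$d[1L]
  r <- sum(keep)
  dinv <- ifelse(keep, 1 / s$d, 0)
  coef <- s$v %*% (dinv * (t(s$u) %*% Y))
  list(coef = coef, rank = r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fmt_num <- function(x) sprintf("%.12g", x)
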