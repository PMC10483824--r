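#' Run-wise z-scoring of time series
#'
#' Within each chunk (run), every feature is independently centered and
#' scaled to unit standard deviation over time (population SD, i.e. the
#' divisor is the number of volumes). Features that are constant within a
#' run are set to zero with a warning rather than dropped, so that
#' `feature_coords` stay aligned with the mask.
#'
#' @param dataset an [mvpa_dataset]; every chunk must hold at least two
#'   time points.
#' @return The dataset with z-scored samples.
#' @export
zscore_timeseries <- function(dataset) {
  stopifnot(inherits(dataset, "mvpa_dataset"))
  X <- dataset$samples
  n_const <- 0L
  for (r in unique(dataset$chunks)) {
    idx <- which(dataset$chunks == r)
    if (length(idx) < 2L)
      stop("chunk ", r, " has fewer than 2 time points; cannot z-score")
    block <- X[idx, , drop = FALSE]
    mu <- colMeans(block)
    centered <- sweep(block, 2L, mu)
    sd0 <- sqrt(colMeans(centered^2))
    const <- sd0 == 0
    n_const <- n_const + sum(const)
    sd0[const] <- 1
    Z <- sweep(centered, 2L, sd0, "/")
    Z[, const] <- 0
    X[idx, ] <- Z
  }
  if (n_const > 0L)
    warning(n_const, " constant feature/run combination(s) set to zero ",
            "during z-scoring")
  dataset$samples <- X
  dataset
}

#' Run-wise polynomial detrending
#'
#' Within each chunk, each feature is replaced by its residual after a
#' least-squares fit of Legendre polynomials up to degree `order`
#' (order 0 removes the mean).
#'
#' @param dataset an [mvpa_dataset].
#' @param order highest polynomial degree (`>= 0`); must be smaller than
#'   every chunk's length.
#' @return The detrended dataset (same shape).
#' @export
detrend <- function(dataset, order = 1L) {
  stopifnot(inherits(dataset, "mvpa_dataset"), order >= 0L)
  X <- dataset$samples
  for (r in unique(dataset$chunks)) {
    idx <- which(dataset$chunks == r)
    if (order >= length(idx))
      stop("detrend order ", order, " >= chunk ", r, " length ",
           length(idx))
    P <- legendre_basis(length(idx), order)
    block <- X[idx, , drop = FALSE]
    coef <- lstsq_minnorm(P, block)$coef
    X[idx, ] <- block - P %*% coef
  }
  dataset$samples <- X
  dataset
}

#' Z-score beta estimates across runs
#'
#' The second normalization of the pipeline: each feature column of the
#' beta matrix is centered and scaled to unit population SD across *all*
#' betas pooled over runs. Generally recommended before RSA; for
#' classification its value depends on the classifier (some SVM wrappers
#' already z-score across runs internally).
#'
#' @param betas a [beta_series] with at least two betas.
#' @return The beta series with z-scored columns; constant columns are set
#'   to zero with a warning.
#' @export
zscore_betas <- function(betas) {
  stopifnot(inherits(betas, "beta_series"))
  B <- betas$betas
  if (nrow(B) < 2L)
    stop("beta z-scoring requires at least two betas")
  mu <- colMeans(B)
  centered <- sweep(B, 2L, mu)
  sd0 <- sqrt(colMeans(centered^2))
  const <- sd0 == 0
  if (any(const))
    warning(sum(const), " constant beta column(s) set to zero during ",
            "z-scoring")
  sd0[const] <- 1
  Z <- sweep(centered, 2L, sd0, "/")
  Z[, const] <- 0
  betas$betas <- Z
  betas
}
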