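#' Representational dissimilarity matrix
#'
#' Pairwise distances between all beta patterns. Samples are ordered
#' condition-major (conditions in the user's list order when recorded,
#' otherwise label-sorted; runs, then trials, within condition), mirroring
#' the conventional RDM layout.
#'
#' Metrics:
#' \describe{
#'   \item{correlation}{\eqn{d_{ij} = 1 - r(\beta_i, \beta_j)} with Pearson
#'     `r` over features; ranges 0 (identical up to a positive affine
#'     transform) to 2 (perfectly anti-correlated).}
#'   \item{euclidean}{\eqn{d_{ij} = \|\beta_i - \beta_j\|_2}.}
#'   \item{mahalanobis}{\eqn{d_{ij} = \sqrt{(\beta_i-\beta_j)^\top
#'     \hat\Sigma^{-1} (\beta_i-\beta_j)}} with a Ledoit–Wolf
#'     shrinkage-regularized feature covariance \eqn{\hat\Sigma} estimated
#'     from the beta matrix (the sample covariance is singular whenever
#'     betas are fewer than features).}
#' }
#'
#' @param betas a [beta_series] with at least two betas (and at least two
#'   features for the correlation metric).
#' @param metric one of `"correlation"`, `"euclidean"`, `"mahalanobis"`.
#' @param conditions optional condition ordering for the rows.
#' @return An object of class `rdm`: `distances` (n x n, symmetric, zero
#'   diagonal), `sample_labels` (condition/run/trial per row), `metric`.
#' @export
compute_rdm <- function(betas, metric = c("correlation", "euclidean",
                                          "mahalanobis"),
                        conditions = NULL) {
  metric <- match.arg(metric)
  stopifnot(inherits(betas, "beta_series"))
  B <- betas$betas
  if (nrow(B) < 2L) stop("an RDM needs at least two beta patterns")
  lab <- betas$labels
  cond_order <- conditions %||% attr(betas, "condition_order") %||%
    sort(unique(lab$condition))
  ord <- order(match(lab$condition, cond_order), lab$run, lab$trial)
  B <- B[ord, , drop = FALSE]
  lab <- lab[ord, , drop = FALSE]
  rownames(lab) <- NULL
  sample_names <- paste0(lab$condition, "/run-", lab$run,
                         ifelse(is.na(lab$trial), "",
                                paste0("/trial-", lab$trial)))

  if (metric == "correlation") {
    if (ncol(B) < 2L)
      stop("correlation distance needs at least two features")
    sds <- apply(B, 1L, stats::sd)
    if (any(sds == 0))
      stop("zero-variance pattern under correlation metric: sample '",
           sample_names[which(sds == 0)[1L]], "'")
    D <- 1 - stats::cor(t(B))
  } else if (metric == "euclidean") {
    D <- as.matrix(stats::dist(B, method = "euclidean"))
  } else {
    S <- lw_shrink_cov(B)
    R <- chol(S)
    W <- t(backsolve(R, t(B), transpose = TRUE))
    D <- as.matrix(stats::dist(W, method = "euclidean"))
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(sample_names, sample_names)
  structure(list(distances = D, sample_labels = lab, metric = metric),
            class = "rdm")
}

# Ledoit-Wolf analytic shrinkage of the feature covariance toward a scaled
# identity. Returns a symmetric positive-definite p x p matrix.
lw_shrink_cov <- function(B) {
  n <- nrow(B); p <- ncol(B)
  Xc <- sweep(B, 2L, colMeans(B))
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - mu * diag(p))^2)
  if (d2 < .Machine$double.eps) {
    Sigma <- mu * diag(p)
  } else {
    b2bar <- 0
    for (k in seq_len(n)) {
      xk <- Xc[k, ]
      b2bar <- b2bar + sum((tcrossprod(xk) - S)^2)
    }
    b2 <- min(b2bar / n^2, d2)
    rho <- b2 / d2
    Sigma <- rho * mu * diag(p) + (1 - rho) * S
  }
  # tiny ridge to guarantee a Cholesky factorization in degenerate cases
  Sigma + diag(p) * (1e-10 * max(mu, .Machine$double.eps))
}

#' Write an RDM to a tab-separated file
#'
#' The first row and column hold the sample labels; numeric cells are
#' written with 12 significant digits so that [read_rdm()] recovers the
#' matrix to within 1e-9.
#'
#' @param rdm an [compute_rdm()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path) {
  stopifnot(inherits(rdm, "rdm"))
  D <- rdm$distances
  if (!length(D)) stop("cannot write an empty RDM")
  labels <- rownames(D)
  lines <- c(paste(c("label", labels), collapse = "\t"),
             vapply(seq_len(nrow(D)), function(i)
               paste(c(labels[i], fmt_num(D[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an RDM written by [write_rdm()]
#'
#' @param path TSV path.
#' @return A numeric matrix with label dimnames.
#' @export
read_rdm <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1L]]
  M <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(M) <- list(labels, colnames(df)[-1L])
  M
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("RDM: %d x %d samples, metric = %s\n",
              nrow(x$distances), ncol(x$distances), x$metric))
  invisible(x)
}
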