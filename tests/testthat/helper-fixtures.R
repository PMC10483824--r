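# Shared fixture builders; everything is generated in code at test time.

# A design_matrix wrapper around an arbitrary numeric matrix whose first
# `n_task` columns are treated as task regressors.
toy_design <- function(X, n_task = ncol(X) - 1L, run_id = 1L) {
  conds <- paste0("c", seq_len(n_task))
  colnames(X) <- c(conds, rep("nuis", ncol(X) - n_task))[seq_len(ncol(X))]
  colnames(X)[ncol(X)] <- "constant"
  structure(list(values = X, names = colnames(X),
                 task_columns = seq_len(n_task),
                 task_info = data.frame(condition = conds,
                                        trial = NA_integer_, onset = 0,
                                        stringsAsFactors = FALSE),
                 run_id = run_id, rank_deficient = FALSE),
            class = "design_matrix")
}

# A beta series of pure Gaussian noise: n_cond conditions x n_runs runs
# (one beta per condition per run), n_feat features.
null_betas <- function(n_cond, n_runs, n_feat, sd = 1) {
  labels <- expand.grid(condition = paste0("c", seq_len(n_cond)),
                        run = seq_len(n_runs), stringsAsFactors = FALSE)
  labels <- labels[order(labels$run, labels$condition), ]
  labels$trial <- NA_integer_
  beta_series(matrix(rnorm(nrow(labels) * n_feat, sd = sd),
                     nrow = nrow(labels)),
              labels)
}

# Separable planted betas: class means far apart relative to noise.
planted_betas <- function(n_cond, n_runs, n_feat, margin = 10, sd = 1) {
  bs <- null_betas(n_cond, n_runs, n_feat, sd = sd)
  proto <- matrix(rnorm(n_cond * n_feat), n_cond)
  idx <- match(bs$labels$condition, paste0("c", seq_len(n_cond)))
  bs$betas <- bs$betas + margin * proto[idx, , drop = FALSE]
  bs
}

# Cheap deterministic classifier honoring the fit/predict contract:
# nearest class mean, ties broken by ascending class order.
mean_classifier <- function() {
  structure(list(
    name = "nearest class mean",
    fit = function(x, y) {
      lev <- levels(droplevels(y))
      M <- do.call(rbind, lapply(lev, function(l)
        colMeans(x[y == l, , drop = FALSE])))
      list(M = M, lev = lev)
    },
    predict = function(model, x) {
      x <- as.matrix(x)
      d <- vapply(seq_len(nrow(model$M)), function(i)
        rowSums(sweep(x, 2L, model$M[i, ])^2), numeric(nrow(x)))
      model$lev[apply(matrix(d, nrow(x)), 1L, which.min)]
    }
  ), class = "mvpa_classifier")
}

# 99% binomial interval around p0 for n trials.
chance_interval <- function(p0, n) {
  half <- stats::qnorm(0.995) * sqrt(p0 * (1 - p0) / n)
  c(p0 - half, p0 + half)
}

# Tiny bold_run on an nx x ny x nz grid.
toy_run <- function(nt, grid = c(4L, 4L, 4L), run_id = 0L, tr = 2,
                    affine = diag(c(3, 3, 3, 1)), data = NULL) {
  if (is.null(data)) data <- array(rnorm(prod(grid) * nt), c(grid, nt))
  bold_run(data, affine, tr, run_id = run_id)
}
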