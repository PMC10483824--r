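#' Beta series
#'
#' The estimated GLM amplitudes that serve as samples for classification and
#' RSA: one row per (condition, run) in per-condition mode, one row per
#' trial in per-trial / LSS mode.
#'
#' @param betas numeric matrix, betas x features.
#' @param labels data frame with columns `condition`, `run`, `trial`
#'   (`trial` is `NA` in per-condition mode), one row per beta.
#' @param feature_coords,affine,grid_dim feature geometry inherited from the
#'   source [mvpa_dataset]; optional.
#' @return An object of class `beta_series`.
#' @export
beta_series <- function(betas, labels, feature_coords = NULL, affine = NULL,
                        grid_dim = NULL) {
  betas <- as.matrix(betas)
  stopifnot(is.data.frame(labels),
            all(c("condition", "run", "trial") %in% names(labels)))
  if (nrow(labels) != nrow(betas))
    stop("labels must have one row per beta")
  rownames(labels) <- NULL
  structure(list(betas = betas, labels = labels,
                 feature_coords = feature_coords, affine = affine,
                 grid_dim = grid_dim),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("Beta series: %d betas x %d features (%d condition(s), %d run(s))\n",
              nrow(x$betas), ncol(x$betas),
              length(unique(x$labels$condition)),
              length(unique(x$labels$run))))
  invisible(x)
}

#' Ordinary least squares fit of a design matrix
#'
#' Estimates \eqn{\hat\beta} minimizing \eqn{\|Y - X\beta\|^2} for every
#' feature column of `Y`. Rank-deficient designs yield the minimum-norm
#' solution with a warning. Only the task-column betas are returned,
#' labeled with their (condition, run, trial) provenance.
#'
#' @param X a `design_matrix` from [build_design_matrix()].
#' @param Y numeric matrix, scans x features, with `nrow(Y)` equal to the
#'   design's scan count.
#' @return A [beta_series] with one row per task column.
#' @export
fit_ols <- function(X, Y) {
  stopifnot(inherits(X, "design_matrix"))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X$values))
    stop("Y has ", nrow(Y), " rows but the design has ", nrow(X$values),
         " scans")
  fit <- lstsq_minnorm(X$values, Y)
  if (fit$rank < ncol(X$values))
    warning("rank-deficient design: returning the minimum-norm ",
            "least-squares solution")
  B <- fit$coef[X$task_columns, , drop = FALSE]
  labels <- data.frame(condition = X$task_info$condition,
                       run = rep(X$run_id, length(X$task_columns)),
                       trial = X$task_info$trial,
                       stringsAsFactors = FALSE)
  beta_series(B, labels)
}

#' Least-squares-single (LSS) per-trial beta estimation
#'
#' For each trial in turn, a dedicated GLM is fitted containing (i) a
#' single-trial regressor for that trial, (ii) one per-condition regressor
#' built from all *remaining* trials (conditions left with no remaining
#' trials are omitted), and (iii) drift and intercept columns; only the
#' single trial's beta is kept. The procedure repeats until every trial of
#' the modeled conditions has an estimate. Betas are returned in onset
#' order.
#'
#' @param events an [event_table] for one run.
#' @param Y numeric matrix, scans x features.
#' @param tr repetition time, seconds.
#' @param spec an [hrf_spec].
#' @param drift_order Legendre drift degree.
#' @param conditions optional conditions of interest; other events only ever
#'   contribute remaining-trial regressors.
#' @param oversample oversampling factor for convolution.
#' @return A [beta_series] with exactly one beta per modeled trial.
#' @export
fit_lss <- function(events, Y, tr, spec = hrf_spec(), drift_order = 0L,
                    conditions = NULL, oversample = 16L) {
  if (!nrow(events)) stop("LSS estimation requires at least one event")
  Y <- as.matrix(Y)
  n_scans <- nrow(Y)
  run_id <- attr(events, "run_id") %||% NA_integer_
  ev <- as.data.frame(events)[order(events$onset), , drop = FALSE]
  if (is.null(conditions)) conditions <- sort(unique(ev$trial_type))
  modeled <- which(ev$trial_type %in% conditions)
  if (!length(modeled))
    stop("no events of the modeled conditions present")
  # trial index within condition, by onset
  trial_idx <- integer(nrow(ev))
  for (cond in unique(ev$trial_type)) {
    rows <- which(ev$trial_type == cond)
    trial_idx[rows] <- seq_along(rows)
  }
  drifts <- if (drift_order >= 1L)
    legendre_basis(n_scans, drift_order)[, -1L, drop = FALSE] else NULL

  out <- matrix(0, nrow = length(modeled), ncol = ncol(Y))
  labels <- vector("list", length(modeled))
  for (m in seq_along(modeled)) {
    i <- modeled[m]
    single <- build_regressor(ev[i, , drop = FALSE], n_scans, tr, spec,
                              oversample)
    cols <- list(single)
    for (cond in sort(unique(ev$trial_type))) {
      rest <- setdiff(which(ev$trial_type == cond), i)
      if (!length(rest)) next
      cols[[length(cols) + 1L]] <-
        build_regressor(ev[rest, , drop = FALSE], n_scans, tr, spec,
                        oversample)
    }
    if (!is.null(drifts)) for (k in seq_len(ncol(drifts)))
      cols[[length(cols) + 1L]] <- drifts[, k]
    cols[[length(cols) + 1L]] <- rep(1, n_scans)
    X <- do.call(cbind, cols)
    fit <- lstsq_minnorm(X, Y)
    out[m, ] <- fit$coef[1L, ]
    labels[[m]] <- data.frame(condition = ev$trial_type[i], run = run_id,
                              trial = trial_idx[i], stringsAsFactors = FALSE)
  }
  beta_series(out, do.call(rbind, labels))
}

#' Estimate a beta series across runs
#'
#' Fits a fixed-effects GLM independently within each run (each run gets
#' its own intercept and drift columns) and stacks the resulting betas in
#' ascending run order. Conditions outside `conditions` are modeled as
#' regressors of no interest and their betas are dropped.
#'
#' @param dataset an [mvpa_dataset] whose `chunks` identify runs.
#' @param events a list of [event_table]s, one per run. Named lists are
#'   matched to run ids by name; unnamed lists positionally to the sorted
#'   distinct chunk values.
#' @param mode `"per-condition"`, `"per-trial"`, or `"lss"`.
#' @param spec an [hrf_spec].
#' @param drift_order Legendre drift degree per run.
#' @param conditions optional ordered conditions of interest.
#' @param oversample oversampling factor for convolution.
#' @return A [beta_series]; labels carry (condition, run, trial).
#' @export
estimate_betas <- function(dataset, events,
                           mode = c("per-condition", "per-trial", "lss"),
                           spec = hrf_spec(), drift_order = 0L,
                           conditions = NULL, oversample = 16L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "mvpa_dataset"))
  if (inherits(events, "event_table")) events <- list(events)
  runs <- sort(unique(dataset$chunks))
  if (!is.null(names(events))) {
    ev_for <- function(r) events[[as.character(r)]]
  } else {
    if (length(events) != length(runs))
      stop("need one event table per run (", length(runs), " runs, ",
           length(events), " tables)")
    ev_for <- function(r) events[[match(r, runs)]]
  }
  tr <- dataset$tr
  if (!is.finite(tr) || tr <= 0)
    stop("dataset has no valid repetition time")
  pieces <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    ev <- ev_for(r)
    if (is.null(ev) || !nrow(ev))
      stop("run ", r, " has no events")
    Y <- dataset$samples[dataset$chunks == r, , drop = FALSE]
    if (mode == "lss") {
      bs <- fit_lss(ev, Y, tr, spec, drift_order, conditions, oversample)
    } else {
      X <- build_design_matrix(ev, mode, n_scans = nrow(Y), tr = tr,
                               spec = spec, drift_order = drift_order,
                               conditions = conditions,
                               oversample = oversample)
      bs <- fit_ols(X, Y)
    }
    bs$labels$run <- r
    pieces[[ri]] <- bs
  }
  betas <- do.call(rbind, lapply(pieces, function(b) b$betas))
  labels <- do.call(rbind, lapply(pieces, function(b) b$labels))
  if (!is.null(conditions)) {
    keep <- labels$condition %in% conditions
    betas <- betas[keep, , drop = FALSE]
    labels <- labels[keep, , drop = FALSE]
  }
  out <- beta_series(betas, labels,
                     feature_coords = dataset$feature_coords,
                     affine = dataset$affine, grid_dim = dataset$grid_dim)
  attr(out, "condition_order") <- conditions
  out
}
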