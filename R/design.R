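#' Build one HRF-convolved task regressor
#'
#' A boxcar (1 during each event's `[onset, onset + duration)`, 0 elsewhere)
#' is constructed on an oversampled grid of step `tr / oversample`,
#' discretely convolved with the HRF sampled on the same grid (scaled by the
#' grid step, so the result approximates the continuous convolution and is
#' stable under the oversampling factor), and then decimated by reading off
#' the values at scan onsets `t = i * tr`.
#'
#' @param events an [event_table] (or data frame with `onset` and
#'   `duration`) holding the events of one label within one run.
#' @param n_scans number of volumes in the run.
#' @param tr repetition time, seconds.
#' @param spec an [hrf_spec].
#' @param oversample integer oversampling factor (`>= 1`).
#' @return Numeric vector of length `n_scans`.
#' @export
build_regressor <- function(events, n_scans, tr, spec = hrf_spec(),
                            oversample = 16L) {
  onset <- events$onset
  duration <- events$duration
  stopifnot(n_scans >= 1L, tr > 0)
  oversample <- as.integer(oversample)
  if (oversample < 1L) stop("oversample must be an integer >= 1")
  if (length(onset) && any(onset < 0)) stop("event onsets must be >= 0")
  run_end <- n_scans * tr
  if (length(onset) && any(onset + duration > run_end + 1e-9)) {
    warning("event(s) extend past the run end (", run_end,
            " s); boxcar clipped to the run")
  }
  dt <- tr / oversample
  n_hi <- n_scans * oversample
  box <- numeric(n_hi)
  t_hi <- (seq_len(n_hi) - 1L) * dt
  for (e in seq_along(onset)) {
    on <- t_hi >= onset[e] - 1e-12 & t_hi < onset[e] + duration[e] - 1e-12
    box[on] <- box[on] + 1
  }
  if (!any(box != 0)) return(numeric(n_scans))
  kern_len <- min(n_hi, as.integer(ceiling(32 / dt)) + 1L)
  h <- sample_hrf(spec, (seq_len(kern_len) - 1L) * dt)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_hi)] * dt
  conv[seq(1L, n_hi, by = oversample)]
}

#' Build a run-level GLM design matrix
#'
#' Task regressors are built per distinct condition (`per-condition` mode)
#' or per event (`per-trial` mode, columns named
#' `<trial_type>#<trial_index>` with the index counting that condition's
#' events by onset). Conditions outside `conditions` (when given) are
#' modeled as per-condition regressors of no interest. Legendre drift
#' columns up to `drift_order` and an intercept (`constant`) complete the
#' design. Column order: task columns (label-sorted, trials in onset
#' order), nuisance condition columns, drifts, intercept.
#'
#' @param events an [event_table] for one run.
#' @param mode `"per-condition"` or `"per-trial"`.
#' @param n_scans,tr,spec,oversample as in [build_regressor()].
#' @param drift_order highest Legendre drift degree (`>= 0`; 0 adds none
#'   beyond the intercept).
#' @param conditions optional ordered character vector of the conditions of
#'   interest; defaults to all distinct `trial_type` values, sorted.
#' @return An object of class `design_matrix`: list with `values`
#'   (scans x regressors), `names`, `task_columns` (indices of the
#'   regressors of interest), `task_info` (condition/trial/onset per task
#'   column), `run_id`, and a `rank_deficient` flag (a warning is emitted
#'   when the numerical rank falls short).
#' @export
build_design_matrix <- function(events, mode = c("per-condition", "per-trial"),
                                n_scans, tr, spec = hrf_spec(),
                                drift_order = 0L, conditions = NULL,
                                oversample = 16L) {
  mode <- match.arg(mode)
  if (!nrow(events)) stop("cannot build a design matrix from zero events")
  stopifnot(drift_order >= 0L)
  all_conds <- sort(unique(events$trial_type))
  if (is.null(conditions)) {
    interest <- all_conds
  } else {
    interest <- as.character(conditions)
    missing <- setdiff(interest, all_conds)
    if (length(missing))
      stop("condition(s) not present in events: ",
           paste(missing, collapse = ", "))
  }
  nuisance <- setdiff(all_conds, interest)

  cols <- list(); names_v <- character(); info <- list()
  for (cond in interest) {
    ev_c <- events[events$trial_type == cond, , drop = FALSE]
    ev_c <- ev_c[order(ev_c$onset), , drop = FALSE]
    if (mode == "per-condition") {
      cols[[length(cols) + 1L]] <-
        build_regressor(ev_c, n_scans, tr, spec, oversample)
      names_v <- c(names_v, cond)
      info[[length(info) + 1L]] <-
        data.frame(condition = cond, trial = NA_integer_,
                   onset = ev_c$onset[1L], stringsAsFactors = FALSE)
    } else {
      for (i in seq_len(nrow(ev_c))) {
        cols[[length(cols) + 1L]] <-
          build_regressor(ev_c[i, , drop = FALSE], n_scans, tr, spec,
                          oversample)
        names_v <- c(names_v, paste0(cond, "#", i))
        info[[length(info) + 1L]] <-
          data.frame(condition = cond, trial = i, onset = ev_c$onset[i],
                     stringsAsFactors = FALSE)
      }
    }
  }
  n_task <- length(cols)
  for (cond in nuisance) {
    ev_c <- events[events$trial_type == cond, , drop = FALSE]
    cols[[length(cols) + 1L]] <-
      build_regressor(ev_c, n_scans, tr, spec, oversample)
    names_v <- c(names_v, paste0("nuisance:", cond))
  }
  if (drift_order >= 1L) {
    L <- legendre_basis(n_scans, drift_order)
    for (k in seq_len(drift_order)) {
      cols[[length(cols) + 1L]] <- L[, k + 1L]
      names_v <- c(names_v, paste0("drift_", k))
    }
  }
  cols[[length(cols) + 1L]] <- rep(1, n_scans)
  names_v <- c(names_v, "constant")
  if (anyDuplicated(names_v))
    stop("internal error: duplicate design column names: ",
         paste(names_v[duplicated(names_v)], collapse = ", "))
  X <- do.call(cbind, cols)
  colnames(X) <- names_v
  rank_def <- mat_rank(X) < ncol(X)
  if (rank_def)
    warning("design matrix is rank-deficient (numerical rank < ",
            ncol(X), ")")
  structure(list(values = X, names = names_v,
                 task_columns = seq_len(n_task),
                 task_info = do.call(rbind, info),
                 run_id = attr(events, "run_id") %||% NA_integer_,
                 rank_deficient = rank_def),
            class = "design_matrix")
}

#' Export a design matrix as TSV for inspection
#'
#' @param design a `design_matrix`.
#' @param path output TSV path (scans x regressors, header = names).
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(design, path) {
  stopifnot(inherits(design, "design_matrix"))
  df <- as.data.frame(design$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
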