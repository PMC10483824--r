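#' Pipeline run configuration
#'
#' Collects everything one invocation needs: where the BIDS-style input
#' lives, where outputs go, which analysis level to run
#' (`participant_prep` concatenates runs; `participant_test` estimates
#' betas and classifies / computes RSA / runs a searchlight), and the
#' analysis flags.
#'
#' @param bids_dir input dataset root.
#' @param output_dir output root (created if missing).
#' @param analysis_level `"participant_prep"` or `"participant_test"`.
#' @param participant_ids character vector of subject labels (without the
#'   `sub-` prefix); `NULL` = all subjects found.
#' @param task,session BIDS entity filters.
#' @param mask ROI mask name looked up under `<output_dir>/masks/`;
#'   mutually exclusive with `searchlight_radius`.
#' @param searchlight_radius sphere radius in voxels; enables searchlight
#'   mode.
#' @param tzscore,bzscore logical: run-wise time-series z-scoring and
#'   across-run beta z-scoring.
#' @param detrend_order polynomial detrend degree, or `NULL` to skip.
#' @param rsa logical: compute an RDM instead of classification.
#' @param conditions_to_classify ordered condition labels of interest.
#' @param estimation `"condition"`, `"trial"`, or `"lss"`.
#' @param n_test_runs runs held out per fold.
#' @param metric RSA distance metric.
#' @param n_permutations permutations for significance testing (0 = skip).
#' @param seed integer seed for the permutation test.
#' @return An object of class `run_config`.
#' @export
run_config <- function(bids_dir, output_dir,
                       analysis_level = c("participant_prep",
                                          "participant_test"),
                       participant_ids = NULL, task = NULL, session = NULL,
                       mask = NULL, searchlight_radius = NULL,
                       tzscore = FALSE, bzscore = FALSE,
                       detrend_order = NULL, rsa = FALSE,
                       conditions_to_classify = NULL,
                       estimation = c("condition", "trial", "lss"),
                       n_test_runs = 1L,
                       metric = c("correlation", "euclidean", "mahalanobis"),
                       n_permutations = 0L, seed = 1L) {
  analysis_level <- match.arg(analysis_level)
  estimation <- match.arg(estimation)
  metric <- match.arg(metric)
  if (!is.null(mask) && !is.null(searchlight_radius))
    stop("--mask and --searchlight are mutually exclusive")
  structure(list(bids_dir = bids_dir, output_dir = output_dir,
                 analysis_level = analysis_level,
                 participant_ids = participant_ids, task = task,
                 session = session, mask = mask,
                 searchlight_radius = searchlight_radius,
                 tzscore = isTRUE(tzscore), bzscore = isTRUE(bzscore),
                 detrend_order = detrend_order, rsa = isTRUE(rsa),
                 conditions_to_classify = conditions_to_classify,
                 estimation = estimation,
                 n_test_runs = as.integer(n_test_runs), metric = metric,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "run_config")
}

pipeline_log <- function(stage, ...) {
  message(sprintf("[mvpadecode] %s: %s", stage,
                  paste(sprintf(...), collapse = "")))
}

find_subjects <- function(config) {
  if (!is.null(config$participant_ids)) return(config$participant_ids)
  dirs <- list.dirs(config$bids_dir, recursive = FALSE, full.names = FALSE)
  subs <- sub("^sub-", "", grep("^sub-", dirs, value = TRUE))
  if (!length(subs)) stop("no sub-* directories found under ",
                          config$bids_dir)
  subs
}

# Locate per-run bold files for one subject; ascending numeric run entity,
# ties broken lexicographically.
find_bold_runs <- function(bids_dir, subject, task = NULL, session = NULL) {
  func_dir <- file.path(bids_dir, paste0("sub-", subject))
  if (!is.null(session)) func_dir <- file.path(func_dir,
                                               paste0("ses-", session))
  func_dir <- file.path(func_dir, "func")
  pattern <- paste0("^sub-", subject,
                    if (!is.null(session)) paste0("_ses-", session) else "",
                    if (!is.null(task)) paste0("_task-", task, "_") else "_",
                    ".*run-[0-9]+_bold\\.nii(\\.gz)?$")
  files <- list.files(func_dir, pattern = pattern, full.names = TRUE)
  if (!length(files))
    stop("no functional runs match pattern '", pattern, "' under ",
         func_dir)
  run_no <- as.integer(sub(".*_run-([0-9]+)_bold\\.nii(\\.gz)?$", "\\1",
                           files))
  ord <- order(run_no, files)
  data.frame(path = files[ord], run_id = run_no[ord],
             stringsAsFactors = FALSE)
}

concat_paths <- function(config, subject) {
  sub_dir <- file.path(config$output_dir, paste0("sub-", subject))
  stem <- paste0("sub-", subject,
                 if (!is.null(config$session))
                   paste0("_ses-", config$session) else "",
                 if (!is.null(config$task))
                   paste0("_task-", config$task) else "")
  list(dir = sub_dir,
       bold = file.path(sub_dir, paste0(stem, "_desc-concat_bold.nii.gz")),
       chunks = file.path(sub_dir, paste0(stem, "_desc-concat_chunks.tsv")))
}

#' Participant preparation: concatenate functional runs
#'
#' For every subject, finds the per-run 4D images, checks that each run has
#' an events table, concatenates the runs in ascending run order into a
#' single gzip-compressed NIfTI under `<output_dir>/sub-<id>/` together
#' with a chunk table TSV (volume index, run id), and creates the
#' `masks/` folder where the user may place ROI masks. Rerunning
#' overwrites deterministically.
#'
#' @param config a [run_config] with `analysis_level = "participant_prep"`.
#' @return Invisibly, per-subject output paths.
#' @export
run_participant_prep <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(config$output_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  out <- list()
  for (subject in find_subjects(config)) {
    runs_df <- find_bold_runs(config$bids_dir, subject, config$task,
                              config$session)
    runs <- vector("list", nrow(runs_df))
    for (i in seq_len(nrow(runs_df))) {
      ev_path <- sub("_bold\\.nii(\\.gz)?$", "_events.tsv",
                     runs_df$path[i])
      if (!file.exists(ev_path))
        stop("missing events file for run ", runs_df$run_id[i],
             " of sub-", subject, " (expected ", ev_path, ")")
      runs[[i]] <- load_bold_run(runs_df$path[i],
                                 run_id = runs_df$run_id[i],
                                 subject = subject, task = config$task,
                                 session = config$session)
    }
    cc <- concatenate_runs(runs)
    paths <- concat_paths(config, subject)
    dir.create(paths$dir, recursive = TRUE, showWarnings = FALSE)
    img <- RNifti::asNifti(cc$data)
    RNifti::sform(img) <- structure(cc$affine, code = 2L)
    # sform carries the spatial scales; only the time step goes in pixdim
    RNifti::pixdim(img) <- c(1, 1, 1, cc$tr)
    RNifti::writeNifti(img, paths$bold)
    utils::write.table(
      data.frame(volume = seq_along(cc$chunks) - 1L, chunk = cc$chunks),
      paths$chunks, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(RepetitionTime = cc$tr),
                         sub("\\.nii\\.gz$", ".json", paths$bold),
                         auto_unbox = TRUE, digits = NA)
    pipeline_log("prep", "sub-%s: %d runs, %d volumes -> %s", subject,
                 nrow(runs_df), length(cc$chunks), paths$bold)
    out[[subject]] <- paths
  }
  invisible(out)
}

#' Participant test: beta estimation and decoding / RSA / searchlight
#'
#' Loads each subject's concatenated data and per-run events, applies the
#' configured normalization (detrend, time-series z-scoring), estimates
#' the beta series in the configured mode, optionally z-scores the betas,
#' and dispatches on the configuration: ROI classification (confusion
#' matrix, cross-validated accuracy, optional permutation test), RSA
#' (RDM TSV), or volumetric searchlight (accuracy map NIfTI). Every mode
#' writes an HTML report under `<output_dir>/sub-<id>/`.
#'
#' @param config a [run_config] with `analysis_level = "participant_test"`.
#' @return Invisibly, a per-subject list of results (fields among `cv`,
#'   `perm`, `rdm`, `map`, plus output paths).
#' @export
run_participant_test <- function(config) {
  stopifnot(inherits(config, "run_config"))
  results <- list()
  for (subject in find_subjects(config)) {
    paths <- concat_paths(config, subject)
    if (!file.exists(paths$bold))
      stop("prep output missing for sub-", subject, " (expected ",
           paths$bold, "); run participant_prep first")
    concat <- load_bold_run(paths$bold)
    chunk_df <- utils::read.delim(paths$chunks)
    cc <- structure(list(data = concat$data, chunks = chunk_df$chunk,
                         affine = concat$affine, tr = concat$tr),
                    class = "bold_concat")

    runs_df <- find_bold_runs(config$bids_dir, subject, config$task,
                              config$session)
    events <- list()
    for (i in seq_len(nrow(runs_df))) {
      ev_path <- sub("_bold\\.nii(\\.gz)?$", "_events.tsv", runs_df$path[i])
      events[[as.character(runs_df$run_id[i])]] <-
        load_events(ev_path, run_id = runs_df$run_id[i], subject = subject,
                    task = config$task, session = config$session)
    }
    conditions <- config$conditions_to_classify
    if (!is.null(conditions)) {
      seen <- unique(unlist(lapply(events, function(e) e$trial_type)))
      missing <- setdiff(conditions, seen)
      if (length(missing))
        stop("condition '", missing[1L],
             "' from conditions_to_classify is absent from the events")
    }

    mask <- NULL
    if (!is.null(config$mask)) {
      cand <- file.path(config$output_dir, "masks",
                        paste0(config$mask, c(".nii.gz", ".nii")))
      hit <- cand[file.exists(cand)]
      if (!length(hit))
        stop("mask '", config$mask, "' not found under ",
             file.path(config$output_dir, "masks"))
      mask <- load_mask(hit[1L], name = config$mask)
    }
    dataset <- apply_mask(cc, mask)
    pipeline_log("dataset", "sub-%s: %d volumes x %d features (%s)",
                 subject, nrow(dataset$samples), ncol(dataset$samples),
                 if (is.null(mask)) "whole brain"
                 else paste0("mask ", mask$name))

    if (!is.null(config$detrend_order)) {
      dataset <- detrend(dataset, config$detrend_order)
      pipeline_log("normalize", "detrend order %d", config$detrend_order)
    }
    if (config$tzscore) {
      dataset <- zscore_timeseries(dataset)
      pipeline_log("normalize", "time-series z-scoring within run")
    }
    mode <- switch(config$estimation, condition = "per-condition",
                   trial = "per-trial", lss = "lss")
    betas <- estimate_betas(dataset, events, mode = mode,
                            conditions = conditions)
    pipeline_log("glm", "estimation %s: %d betas x %d features", mode,
                 nrow(betas$betas), ncol(betas$betas))
    if (config$bzscore) {
      betas <- zscore_betas(betas)
      pipeline_log("normalize", "beta z-scoring across runs")
    }

    res <- list(subject = subject, config = config)
    dir.create(paths$dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(config$searchlight_radius)) {
      sl_mask <- mask %||%
        mask_volume(array(1, dim = dataset$grid_dim),
                    affine = dataset$affine, name = "wholebrain")
      folds <- make_folds(betas$labels$run, config$n_test_runs)
      map <- run_searchlight(betas, sl_mask, config$searchlight_radius,
                             folds = folds)
      map_path <- file.path(paths$dir,
                            paste0("sub-", subject,
                                   "_desc-searchlight_accuracy.nii.gz"))
      write_map(map, map_path)
      pipeline_log("searchlight", "radius %g voxels -> %s",
                   config$searchlight_radius, map_path)
      res$map <- map
      res$map_path <- map_path
    } else if (config$rsa) {
      rdm <- compute_rdm(betas, metric = config$metric,
                         conditions = conditions)
      rdm_path <- file.path(paths$dir,
                            paste0("sub-", subject, "_desc-rsa_rdm.tsv"))
      write_rdm(rdm, rdm_path)
      pipeline_log("rsa", "metric %s: %d x %d RDM -> %s", config$metric,
                   nrow(rdm$distances), ncol(rdm$distances), rdm_path)
      res$rdm <- rdm
      res$rdm_path <- rdm_path
    } else {
      folds <- make_folds(betas$labels$run, config$n_test_runs)
      cv <- cross_validate(betas, folds)
      pipeline_log("decode", "%d folds (n_test %d): accuracy %.4f",
                   length(folds$folds), config$n_test_runs,
                   cv$overall_accuracy)
      res$cv <- cv
      acc_path <- file.path(paths$dir,
                            paste0("sub-", subject,
                                   "_desc-classification_accuracy.tsv"))
      utils::write.table(
        data.frame(fold = seq_along(cv$per_fold_accuracy),
                   test_runs = vapply(folds$folds, function(f)
                     paste(f$test, collapse = ","), character(1)),
                   accuracy = fmt_num(cv$per_fold_accuracy)),
        acc_path, sep = "\t", quote = FALSE, row.names = FALSE)
      res$accuracy_path <- acc_path
      if (config$n_permutations > 0L) {
        res$perm <- permutation_test(betas, folds,
                                     n_permutations = config$n_permutations,
                                     seed = config$seed)
        pipeline_log("decode", "permutation test N = %d: p = %.5g",
                     config$n_permutations, res$perm$p_value)
      }
    }
    html_path <- file.path(paths$dir,
                           paste0("sub-", subject, "_report.html"))
    write_html_report(res, html_path)
    res$report_path <- html_path
    results[[subject]] <- res
  }
  invisible(results)
}
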