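#' Specification of a synthetic BIDS-style dataset
#'
#' Describes a blocked task fMRI experiment with a planted multivariate
#' code: each condition carries a fixed random weight pattern over a ball
#' of "informative" voxels, and every voxel's time series is the sum of
#' the HRF-convolved event boxcars weighted by that pattern, a linear
#' drift, and i.i.d. Gaussian noise. Generation is fully reproducible from
#' `seed`.
#'
#' @param n_subjects,n_runs,n_conditions,trials_per_condition_per_run
#'   experiment sizes (all `>= 1`).
#' @param grid 3-element voxel grid dimensions.
#' @param tr repetition time, seconds.
#' @param event_duration block duration, seconds.
#' @param inter_trial_interval rest between consecutive blocks, seconds.
#' @param effect_amplitude planted signal amplitude (0 = null data).
#' @param noise_sd Gaussian noise SD (`> 0`).
#' @param informative_center,informative_radius ball of informative voxels
#'   (0-based center; default: grid center, radius 2).
#' @param drift_amplitude peak-to-peak/2 amplitude of the linear drift.
#' @param ar_coef optional AR(1) coefficient for temporally correlated
#'   noise (0 = white, the default).
#' @param conditions optional condition labels (default `cond01`, ...).
#' @param task task label used in file names.
#' @param seed integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 1L, n_runs = 6L, n_conditions = 4L,
                           trials_per_condition_per_run = 1L,
                           grid = c(8L, 8L, 8L), tr = 2.5,
                           event_duration = 9, inter_trial_interval = 6,
                           effect_amplitude = 3, noise_sd = 1,
                           informative_center = NULL,
                           informative_radius = 2,
                           drift_amplitude = 0, ar_coef = 0,
                           conditions = NULL, task = "synth", seed = 1L) {
  stopifnot(n_subjects >= 1L, n_runs >= 1L, n_conditions >= 1L,
            trials_per_condition_per_run >= 1L, length(grid) == 3L,
            tr > 0, event_duration > 0, inter_trial_interval >= 0,
            noise_sd > 0, informative_radius >= 0)
  if (is.null(informative_center)) informative_center <- floor(grid / 2)
  if (any(informative_center - informative_radius < 0) ||
      any(informative_center + informative_radius > grid - 1))
    stop("grid too small for the informative ball (center ",
         paste(informative_center, collapse = ","), ", radius ",
         informative_radius, ")")
  if (is.null(conditions))
    conditions <- sprintf("cond%02d", seq_len(n_conditions))
  stopifnot(length(conditions) == n_conditions)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_runs = as.integer(n_runs),
                 n_conditions = as.integer(n_conditions),
                 trials_per_condition_per_run =
                   as.integer(trials_per_condition_per_run),
                 grid = as.integer(grid), tr = tr,
                 event_duration = event_duration,
                 inter_trial_interval = inter_trial_interval,
                 effect_amplitude = effect_amplitude, noise_sd = noise_sd,
                 informative_center = as.integer(informative_center),
                 informative_radius = informative_radius,
                 drift_amplitude = drift_amplitude, ar_coef = ar_coef,
                 conditions = conditions, task = task,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Preset emulating a classic 8-category object-viewing block design
#'
#' Eight stimulus categories shown in one block per condition per run over
#' twelve runs — the structure of the seminal ventral-temporal object
#' decoding experiments. With the default amplitude-to-noise ratio of 5
#' the planted patterns are reliably decodable; set `effect_amplitude = 0`
#' for null data.
#'
#' @param effect_amplitude,noise_sd,seed passed to [synthetic_spec()].
#' @return A [synthetic_spec] with 8 conditions and 12 runs.
#' @export
haxby_like_spec <- function(effect_amplitude = 5, noise_sd = 1, seed = 20L) {
  synthetic_spec(
    n_subjects = 1L, n_runs = 12L, n_conditions = 8L,
    trials_per_condition_per_run = 1L, grid = c(8L, 8L, 8L), tr = 2.5,
    event_duration = 9, inter_trial_interval = 6,
    effect_amplitude = effect_amplitude, noise_sd = noise_sd,
    conditions = c("bottle", "cat", "chair", "face", "house", "scissors",
                   "scrambledpix", "shoe"),
    task = "objectviewing", seed = seed)
}

# 0-based coordinates of the informative ball, in row-major feature order.
informative_coords <- function(spec) {
  g <- spec$grid
  ctr <- spec$informative_center
  r <- spec$informative_radius
  rng <- function(c, n) max(0L, c - ceiling(r)):min(n - 1L, c + ceiling(r))
  co <- as.matrix(expand.grid(i = rng(ctr[1L], g[1L]),
                              j = rng(ctr[2L], g[2L]),
                              k = rng(ctr[3L], g[3L])))
  keep <- (co[, 1L] - ctr[1L])^2 + (co[, 2L] - ctr[2L])^2 +
    (co[, 3L] - ctr[3L])^2 <= r^2 + 1e-9
  co <- co[keep, , drop = FALSE]
  co[order(co[, 1L], co[, 2L], co[, 3L]), , drop = FALSE]
}

#' Binary mask of a synthetic spec's informative voxels
#'
#' Convenient ROI for end-to-end tests: place it in the pipeline's
#' `masks/` folder to restrict analysis to the planted pattern.
#'
#' @param spec a [synthetic_spec].
#' @param name mask label.
#' @return A [mask_volume] on the spec's grid (3 mm isotropic affine).
#' @export
informative_mask <- function(spec, name = "planted") {
  arr <- array(0, dim = spec$grid)
  co <- informative_coords(spec)
  arr[co + 1L] <- 1
  mask_volume(arr, affine = diag(c(3, 3, 3, 1)), name = name)
}

synth_run_schedule <- function(spec, order_perm) {
  blocks <- rep(spec$conditions, each = spec$trials_per_condition_per_run)
  blocks <- blocks[order_perm]
  lead_in <- 12
  step <- spec$event_duration + spec$inter_trial_interval
  onsets <- lead_in + (seq_along(blocks) - 1L) * step
  event_table(onset = onsets,
              duration = rep(spec$event_duration, length(blocks)),
              trial_type = blocks, task = spec$task)
}

synth_n_scans <- function(spec) {
  nb <- spec$n_conditions * spec$trials_per_condition_per_run
  total <- 12 + nb * (spec$event_duration + spec$inter_trial_interval) + 12
  as.integer(ceiling(total / spec$tr))
}

#' Generate a synthetic BIDS-style dataset on disk
#'
#' Writes, for each subject and run,
#' `sub-XX/func/sub-XX_task-<task>_run-RR_bold.nii.gz`, the matching
#' `_events.tsv` and a JSON sidecar with `RepetitionTime`, plus a
#' `ground_truth_synthetic.json` at the root recording the planted
#' condition weight patterns, informative voxel coordinates and per-run
#' block orders. The block order is a fixed schedule with constant
#' inter-trial interval, permuted per run from the seed.
#'
#' @param spec a [synthetic_spec].
#' @param out_dir writable output directory (created if missing).
#' @return Invisibly, a list with the output `dir`, the `truth` record and
#'   per-subject file paths.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  g <- spec$grid
  nvox <- prod(g)
  co <- informative_coords(spec)
  lin_inf <- 1L + co[, 1L] + g[1L] * (co[, 2L] + g[2L] * co[, 3L])
  n_scans <- synth_n_scans(spec)
  affine <- diag(c(3, 3, 3, 1))
  spec_hrf <- hrf_spec()
  nb <- spec$n_conditions * spec$trials_per_condition_per_run

  truth <- list(conditions = spec$conditions,
                informative_voxels = unname(apply(co, 1L, function(x)
                  as.list(as.integer(x)), simplify = FALSE)),
                effect_amplitude = spec$effect_amplitude,
                noise_sd = spec$noise_sd, seed = spec$seed,
                tr = spec$tr, n_scans_per_run = n_scans,
                weights = list(), block_orders = list())
  subjects <- sprintf("%02d", seq_len(spec$n_subjects))
  paths <- list()

  with_seed(spec$seed, {
    W <- matrix(stats::rnorm(spec$n_conditions * nrow(co)),
                nrow = spec$n_conditions)
    truth$weights <- lapply(seq_len(spec$n_conditions),
                             function(c) unname(W[c, ]))
    for (s in subjects) {
      func_dir <- file.path(out_dir, paste0("sub-", s), "func")
      dir.create(func_dir, recursive = TRUE, showWarnings = FALSE)
      sub_paths <- list()
      for (r in seq_len(spec$n_runs)) {
        perm <- sample.int(nb)
        truth$block_orders[[paste0("sub-", s)]][[r]] <- perm
        ev <- synth_run_schedule(spec, perm)
        attr(ev, "run_id") <- r
        attr(ev, "subject") <- s

        # condition regressors at scan resolution
        regs <- vapply(spec$conditions, function(cond)
          build_regressor(ev[ev$trial_type == cond, , drop = FALSE],
                          n_scans, spec$tr, spec_hrf), numeric(n_scans))
        noise <- matrix(stats::rnorm(nvox * n_scans, sd = spec$noise_sd),
                        nrow = nvox)
        if (spec$ar_coef != 0) {
          noise <- t(apply(noise, 1L, function(x)
            as.numeric(stats::filter(x, spec$ar_coef, method = "recursive"))))
        }
        M <- noise
        if (spec$drift_amplitude != 0) {
          drift <- spec$drift_amplitude *
            seq(-1, 1, length.out = n_scans)
          M <- M + matrix(drift, nrow = nvox, ncol = n_scans, byrow = TRUE)
        }
        if (spec$effect_amplitude != 0) {
          signal <- spec$effect_amplitude * t(W) %*% t(regs)  # inf vox x t
          M[lin_inf, ] <- M[lin_inf, ] + signal
        }
        stem <- sprintf("sub-%s_task-%s_run-%02d", s, spec$task, r)
        bold_path <- file.path(func_dir, paste0(stem, "_bold.nii.gz"))
        img <- RNifti::asNifti(array(M, dim = c(g, n_scans)))
        RNifti::sform(img) <- structure(affine, code = 2L)
        RNifti::pixdim(img) <- c(1, 1, 1, spec$tr)
        RNifti::writeNifti(img, bold_path)
        jsonlite::write_json(list(RepetitionTime = spec$tr,
                                  TaskName = spec$task),
                             file.path(func_dir, paste0(stem, "_bold.json")),
                             auto_unbox = TRUE, digits = NA)
        write_events(ev, file.path(func_dir, paste0(stem, "_events.tsv")))
        sub_paths[[r]] <- bold_path
      }
      paths[[paste0("sub-", s)]] <- sub_paths
    }
  })
  jsonlite::write_json(truth,
                       file.path(out_dir, "ground_truth_synthetic.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, truth = truth, paths = paths))
}
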