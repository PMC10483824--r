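small_spec <- function(...) {
  synthetic_spec(n_runs = 4L, n_conditions = 3L, grid = c(6L, 6L, 6L),
                 informative_radius = 1.5, ...)
}

test_that("generation is deterministic from the seed", {
  spec <- small_spec(seed = 9L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(spec, d1)
  generate_dataset(spec, d2)
  ev1 <- file.path(d1, "sub-01", "func",
                   "sub-01_task-synth_run-01_events.tsv")
  ev2 <- file.path(d2, "sub-01", "func",
                   "sub-01_task-synth_run-01_events.tsv")
  expect_identical(readLines(ev1), readLines(ev2))
  b1 <- load_bold_run(sub("_events\\.tsv", "_bold.nii.gz", ev1))
  b2 <- load_bold_run(sub("_events\\.tsv", "_bold.nii.gz", ev2))
  expect_lt(max(abs(b1$data - b2$data)), 1e-12)
})

test_that("the generated tree has the contracted layout and loads cleanly", {
  spec <- small_spec(trials_per_condition_per_run = 2L, seed = 10L)
  dir <- withr::local_tempdir()
  generate_dataset(spec, dir)
  func <- file.path(dir, "sub-01", "func")
  bolds <- list.files(func, pattern = "_bold\\.nii\\.gz$")
  expect_length(bolds, 4L)
  expect_no_warning({
    for (r in 1:4) {
      stem <- sprintf("sub-01_task-synth_run-%02d", r)
      ev <- load_events(file.path(func, paste0(stem, "_events.tsv")))
      expect_equal(nrow(ev), 3L * 2L)
      expect_setequal(unique(ev$trial_type), spec$conditions)
      run <- load_bold_run(file.path(func, paste0(stem, "_bold.nii.gz")))
      expect_equal(run$tr, spec$tr)
    }
  })
  expect_true(file.exists(file.path(dir, "ground_truth_synthetic.json")))
})

test_that("the 8-condition 12-run preset yields 96 per-condition betas", {
  spec <- haxby_like_spec()
  expect_equal(spec$n_conditions, 8L)
  expect_equal(spec$n_runs, 12L)
  expect_length(spec$conditions, 8L)
  # counting contract without a full generation: 8 x 12 betas
  dir <- withr::local_tempdir()
  small <- small_spec(seed = 11L)
  generate_dataset(small, dir)
  runs <- lapply(1:4, function(r) {
    stem <- sprintf("sub-01_task-synth_run-%02d", r)
    load_bold_run(file.path(dir, "sub-01", "func",
                            paste0(stem, "_bold.nii.gz")), run_id = r)
  })
  evs <- lapply(1:4, function(r) {
    stem <- sprintf("sub-01_task-synth_run-%02d", r)
    load_events(file.path(dir, "sub-01", "func",
                          paste0(stem, "_events.tsv")), run_id = r)
  })
  ds <- apply_mask(concatenate_runs(runs), informative_mask(small))
  bs <- estimate_betas(ds, evs, "per-condition")
  expect_equal(nrow(bs$betas), 4L * 3L)
})

test_that("planted-ROI accuracy does not decrease along an amplitude grid", {
  amps <- c(0, 0.3, 1.5, 6)
  accs <- vapply(amps, function(a) {
    dir <- withr::local_tempdir()
    spec <- small_spec(effect_amplitude = a, seed = 12L)
    generate_dataset(spec, dir)
    runs <- lapply(1:4, function(r) {
      stem <- sprintf("sub-01_task-synth_run-%02d", r)
      load_bold_run(file.path(dir, "sub-01", "func",
                              paste0(stem, "_bold.nii.gz")), run_id = r)
    })
    evs <- lapply(1:4, function(r) {
      stem <- sprintf("sub-01_task-synth_run-%02d", r)
      load_events(file.path(dir, "sub-01", "func",
                            paste0(stem, "_events.tsv")), run_id = r)
    })
    ds <- apply_mask(concatenate_runs(runs), informative_mask(spec))
    bs <- zscore_betas(estimate_betas(ds, evs, "per-condition"))
    cross_validate(bs)$overall_accuracy
  }, numeric(1))
  # monotone non-decreasing within one binomial standard error
  se <- sqrt(0.5 * 0.5 / 12)
  expect_true(all(diff(accs) >= -se))
  expect_gt(accs[4], accs[1])
})

test_that("LSS and per-trial OLS recover planted per-trial amplitudes", {
  # trials >= 40 s apart, nearly noiseless
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_runs = 1L, n_conditions = 2L,
                         trials_per_condition_per_run = 3L,
                         grid = c(6L, 6L, 6L), informative_radius = 1.5,
                         event_duration = 2, inter_trial_interval = 40,
                         effect_amplitude = 4, noise_sd = 1e-4, seed = 13L)
  generate_dataset(spec, dir)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth_synthetic.json"),
                               simplifyVector = TRUE)
  stem <- "sub-01_task-synth_run-01"
  run <- load_bold_run(file.path(dir, "sub-01", "func",
                                 paste0(stem, "_bold.nii.gz")), run_id = 1L)
  ev <- load_events(file.path(dir, "sub-01", "func",
                              paste0(stem, "_events.tsv")), run_id = 1L)
  ds <- apply_mask(run, informative_mask(spec))
  for (mode in c("per-trial", "lss")) {
    bs <- estimate_betas(ds, list(ev), mode)
    # planted per-trial amplitude at voxel v is amplitude * w_c(v)
    W <- truth$weights
    if (is.list(W)) W <- do.call(rbind, W)
    idx <- match(bs$labels$condition, truth$conditions)
    planted <- spec$effect_amplitude * W[idx, , drop = FALSE]
    expect_gt(cor(as.vector(bs$betas), as.vector(planted)), 0.99)
  }
})

test_that("degenerate specs are rejected", {
  expect_error(synthetic_spec(grid = c(3L, 3L, 3L), informative_radius = 4),
               "too small")
  expect_error(synthetic_spec(noise_sd = 0), "noise_sd")
})
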