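test_that("OLS matches the normal-equations oracle and recovers noiseless betas", {
  set.seed(11)
  for (rep in 1:10) {
    Xm <- cbind(matrix(rnorm(8 * 2), 8), 1)
    X <- toy_design(Xm, n_task = 2L)
    Y <- matrix(rnorm(8 * 2), 8)
    bs <- fit_ols(X, Y)
    oracle <- solve(t(Xm) %*% Xm, t(Xm) %*% Y)
    expect_lt(max(abs(bs$betas - oracle[1:2, ])), 1e-8)
  }
  # noiseless identifiability
  Xm <- cbind(matrix(rnorm(20 * 3), 20), 1)
  beta_true <- matrix(rnorm(4 * 5), 4)
  Y <- Xm %*% beta_true
  bs <- fit_ols(toy_design(Xm, n_task = 3L), Y)
  expect_lt(max(abs(bs$betas - beta_true[1:3, ])), 1e-10)

  expect_error(fit_ols(toy_design(Xm, 3L), Y[1:5, ]), "rows")
})

test_that("duplicated columns give the minimum-norm solution with a warning", {
  set.seed(12)
  base <- matrix(rnorm(10 * 2), 10)
  Xm <- cbind(base[, 1], base[, 1], base[, 2], 1)
  X <- toy_design(Xm, n_task = 3L)
  Y <- matrix(rnorm(10), 10)
  expect_warning(bs <- fit_ols(X, Y), "minimum-norm")
  # min-norm solution splits the duplicated column's weight evenly
  expect_lt(abs(bs$betas[1, 1] - bs$betas[2, 1]), 1e-8)
  # and the projection still matches the full-rank reduced design
  res <- Y - cbind(base, 1) %*% qr.coef(qr(cbind(base, 1)), Y)
  expect_lt(max(abs(t(Xm) %*% res)), 1e-6)
})

test_that("OLS residuals are orthogonal to the design and betas scale with Y", {
  set.seed(13)
  for (rep in 1:5) {
    Xm <- cbind(matrix(rnorm(15 * 3), 15), 1)
    X <- toy_design(Xm, n_task = 3L)
    Y <- matrix(rnorm(15 * 4), 15)
    full <- mvpadecode:::lstsq_minnorm(Xm, Y)$coef
    expect_lt(max(abs(t(Xm) %*% (Y - Xm %*% full))), 1e-6)
    b1 <- fit_ols(X, Y)$betas
    b3 <- fit_ols(X, 3 * Y)$betas
    expect_lt(max(abs(b3 - 3 * b1)), 1e-8)
  }
})

test_that("LSS equals per-condition OLS with a single trial per condition", {
  set.seed(14)
  ev <- event_table(onset = c(10, 40), duration = c(4, 4),
                    trial_type = c("a", "b"), run_id = 1L)
  n <- 40L; tr <- 2
  Y <- matrix(rnorm(n * 3), n)
  lss <- fit_lss(ev, Y, tr)
  X <- build_design_matrix(ev, "per-condition", n, tr)
  ols <- fit_ols(X, Y)
  expect_lt(max(abs(lss$betas - ols$betas)), 1e-10)
  expect_equal(lss$labels$condition, c("a", "b"))
})

test_that("LSS matches per-trial OLS (LSA) when trials are 40 s apart", {
  set.seed(15)
  ev <- event_table(onset = c(10, 52, 94, 136, 178, 220),
                    duration = rep(2, 6),
                    trial_type = rep(c("a", "b"), 3), run_id = 1L)
  n <- 130L; tr <- 2
  Y <- matrix(rnorm(n * 4), n)
  lss <- fit_lss(ev, Y, tr)
  lsa <- fit_ols(build_design_matrix(ev, "per-trial", n, tr), Y)
  # LSA betas come label-major; reorder by onset to align with LSS output
  onsets_lsa <- vapply(seq_len(6), function(i) {
    evc <- ev[ev$trial_type == lsa$labels$condition[i], ]
    evc$onset[lsa$labels$trial[i]]
  }, numeric(1))
  expect_equal(nrow(lss$betas), 6L)
  expect_lt(max(abs(lss$betas - lsa$betas[order(onsets_lsa), ])), 1e-3)

  expect_error(fit_lss(ev[0, ], Y, tr), "at least one event")
})

test_that("estimate_betas fits per run, stacks in run order, drops nuisance", {
  set.seed(16)
  n_scans <- 30L
  evs <- lapply(1:2, function(r)
    event_table(onset = c(5, 20, 35), duration = rep(3, 3),
                trial_type = c("a", "b", "c"), run_id = r))
  samples <- matrix(rnorm(2 * n_scans * 5), 2 * n_scans)
  ds <- mvpa_dataset(samples, chunks = rep(1:2, each = n_scans), tr = 2)
  bs <- estimate_betas(ds, evs, "per-condition")
  expect_equal(nrow(bs$betas), 6L)  # 2 runs x 3 conditions
  expect_equal(bs$labels$run, rep(1:2, each = 3))

  # per-run independence: perturbing run 2 leaves run 1 betas unchanged
  ds2 <- ds
  ds2$samples[ds$chunks == 2, ] <- 99 * ds2$samples[ds$chunks == 2, ]
  bs2 <- estimate_betas(ds2, evs, "per-condition")
  expect_identical(bs$betas[bs$labels$run == 1, ],
                   bs2$betas[bs2$labels$run == 1, ])

  # nuisance conditions dropped from the output
  bs3 <- estimate_betas(ds, evs, "per-condition", conditions = c("c", "a"))
  expect_setequal(unique(bs3$labels$condition), c("a", "c"))
  expect_equal(nrow(bs3$betas), 4L)

  expect_error(estimate_betas(ds, list(evs[[1]], evs[[2]][0, ]),
                              "per-condition"), "no events")
})

test_that("noiseless synthetic responses are recovered exactly per run", {
  set.seed(17)
  n_scans <- 40L; tr <- 2
  evs <- lapply(1:2, function(r)
    event_table(onset = c(8, 30, 52), duration = rep(4, 3),
                trial_type = c("a", "b", "a"), run_id = r))
  beta_true <- matrix(rnorm(2 * 3), 2)  # condition x feature
  samples <- do.call(rbind, lapply(1:2, function(r) {
    X <- build_design_matrix(evs[[r]], "per-condition", n_scans, tr)
    X$values[, 1:2] %*% beta_true + 0
  }))
  ds <- mvpa_dataset(samples, chunks = rep(1:2, each = n_scans), tr = tr)
  bs <- estimate_betas(ds, evs, "per-condition")
  expect_lt(max(abs(bs$betas - beta_true[rep(1:2, 2), ])), 1e-10)
})

test_that("per-condition, per-trial and LSS coincide with one trial per condition", {
  set.seed(18)
  ev <- event_table(onset = c(6, 36), duration = c(4, 4),
                    trial_type = c("a", "b"), run_id = 1L)
  n <- 36L; tr <- 2
  ds <- mvpa_dataset(matrix(rnorm(n * 3), n), chunks = rep(1L, n), tr = tr)
  b_cond <- estimate_betas(ds, list(ev), "per-condition")$betas
  b_trial <- estimate_betas(ds, list(ev), "per-trial")$betas
  b_lss <- estimate_betas(ds, list(ev), "lss")$betas
  expect_lt(max(abs(b_cond - b_trial)), 1e-10)
  expect_lt(max(abs(b_cond - b_lss)), 1e-10)
})
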