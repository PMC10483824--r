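two_sample_betas <- function(x1, x2) {
  beta_series(rbind(x1, x2),
              data.frame(condition = c("a", "b"), run = c(1L, 1L),
                         trial = NA_integer_))
}

test_that("correlation distance hits its extremes and range", {
  x <- c(1, -2, 3, 0.5)
  same <- two_sample_betas(x, 2 * x + 5)   # affine transform, a > 0
  expect_equal(compute_rdm(same, "correlation")$distances[1, 2], 0)

  xc <- x - mean(x)
  anti <- two_sample_betas(xc, -xc)
  expect_equal(compute_rdm(anti, "correlation")$distances[1, 2], 2)

  set.seed(41)
  bs <- null_betas(4, 3, 6)
  D <- compute_rdm(bs, "correlation")$distances
  expect_true(all(D >= 0 - 1e-12 & D <= 2 + 1e-12))
})

test_that("RDMs are symmetric with zero diagonal and oracle-exact distances", {
  set.seed(42)
  bs <- null_betas(3, 2, 4)
  for (metric in c("correlation", "euclidean")) {
    D <- compute_rdm(bs, metric)$distances
    expect_lt(max(abs(D - t(D))), 1e-10)
    expect_equal(unname(diag(D)), rep(0, 6))
  }
  # 3-4-5 triangle
  tri <- two_sample_betas(c(0, 0), c(3, 4))
  expect_equal(compute_rdm(tri, "euclidean")$distances[1, 2], 5)

  # double-loop oracles
  B <- matrix(rnorm(6 * 4), 6)
  bs6 <- beta_series(B, data.frame(condition = paste0("c", 1:6),
                                   run = 1L, trial = NA_integer_))
  D_e <- compute_rdm(bs6, "euclidean")$distances
  D_c <- compute_rdm(bs6, "correlation")$distances
  for (i in 1:6) for (j in 1:6) {
    expect_lt(abs(D_e[i, j] - sqrt(sum((B[i, ] - B[j, ])^2))), 1e-10)
    expect_lt(abs(D_c[i, j] - (1 - cor(B[i, ], B[j, ]))), 1e-10)
  }
})

test_that("Mahalanobis distances use the shrinkage covariance consistently", {
  set.seed(43)
  B <- matrix(rnorm(8 * 5), 8)
  bs <- beta_series(B, data.frame(condition = paste0("c", 1:8), run = 1L,
                                  trial = NA_integer_))
  D <- compute_rdm(bs, "mahalanobis")$distances
  S <- mvpadecode:::lw_shrink_cov(B)
  for (i in 1:8) for (j in 1:8) {
    d2 <- t(B[i, ] - B[j, ]) %*% solve(S) %*% (B[i, ] - B[j, ])
    expect_lt(abs(D[i, j] - sqrt(as.numeric(d2))), 1e-8)
  }
  expect_true(all(D >= 0))
  # works even when betas << features (singular sample covariance)
  wide <- beta_series(matrix(rnorm(4 * 50), 4),
                      data.frame(condition = paste0("c", 1:4), run = 1L,
                                 trial = NA_integer_))
  expect_silent(compute_rdm(wide, "mahalanobis"))
})

test_that("RDM invariances: feature permutation, affine transforms, triangles", {
  set.seed(44)
  bs <- null_betas(4, 3, 10)
  perm <- sample(10)
  bsp <- bs; bsp$betas <- bs$betas[, perm]
  for (metric in c("correlation", "euclidean", "mahalanobis")) {
    expect_equal(compute_rdm(bs, metric)$distances,
                 compute_rdm(bsp, metric)$distances, tolerance = 1e-10)
  }
  # per-sample positive affine transforms leave correlation distances alone
  bsa <- bs
  for (i in seq_len(nrow(bsa$betas)))
    bsa$betas[i, ] <- runif(1, 0.5, 3) * bsa$betas[i, ] + rnorm(1)
  expect_equal(compute_rdm(bs, "correlation")$distances,
               compute_rdm(bsa, "correlation")$distances, tolerance = 1e-9)
  # Euclidean triangle inequality over all triples
  D <- compute_rdm(bs, "euclidean")$distances
  n <- nrow(D)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-10)
})

test_that("RDM rows are condition-major and zero-variance patterns error", {
  set.seed(45)
  bs <- null_betas(2, 2, 4)
  rdm <- compute_rdm(bs, "correlation", conditions = c("c2", "c1"))
  expect_equal(rdm$sample_labels$condition, c("c2", "c2", "c1", "c1"))
  expect_equal(rdm$sample_labels$run, c(1L, 2L, 1L, 2L))

  flat <- two_sample_betas(c(1, 1, 1), c(1, 2, 3))
  expect_error(compute_rdm(flat, "correlation"), "zero-variance.*a")
})

test_that("RDM TSV write/read round trip and label counts", {
  set.seed(46)
  bs <- null_betas(8, 12, 5)
  rdm <- compute_rdm(bs, "correlation")
  expect_equal(dim(rdm$distances), c(96L, 96L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rdm(rdm, path)
  back <- read_rdm(path)
  expect_equal(dim(back), c(96L, 96L))
  expect_lt(max(abs(back - rdm$distances)), 1e-9)
  expect_equal(rownames(back), rownames(rdm$distances))

  empty <- structure(list(distances = matrix(numeric(), 0, 0)),
                     class = "rdm")
  expect_error(write_rdm(empty, path), "empty")
})
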