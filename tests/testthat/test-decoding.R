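test_that("fold schemes enumerate all leave-n-out combinations", {
  f1 <- make_folds(rep(0:11, each = 2), n_test = 1L)
  expect_equal(length(f1$folds), 12L)
  expect_true(all(vapply(f1$folds, function(f)
    length(f$train) == 11L && length(f$test) == 1L, logical(1))))

  f2 <- make_folds(1:4, n_test = 2L)
  oracle <- combn(1:4, 2, simplify = FALSE)  # brute-force enumeration
  expect_equal(length(f2$folds), 6L)
  expect_equal(lapply(f2$folds, `[[`, "test"), oracle)
  for (f in f2$folds) {
    expect_length(intersect(f$train, f$test), 0L)
    expect_setequal(union(f$train, f$test), 1:4)
  }

  expect_error(make_folds(1:4, 4L), "n_test")
  expect_error(make_folds(rep(1, 5)), "2 distinct")
})

test_that("separable planted patterns are decoded perfectly", {
  set.seed(31)
  bs <- planted_betas(4, 6, 10, margin = 20)
  cv <- cross_validate(bs)
  expect_equal(cv$overall_accuracy, 1.0)
  expect_true(all(cv$confusion[upper.tri(cv$confusion)] == 0))
  expect_true(all(cv$confusion[lower.tri(cv$confusion)] == 0))
  expect_equal(cv$chance_level, 0.25)
  expect_length(cv$per_fold_accuracy, 6L)
  # confusion column sums = test samples per class
  expect_equal(unname(colSums(cv$confusion)), rep(6L, 4))
})

test_that("cross-validation is invariant to sample order and keyed on chunks", {
  set.seed(32)
  bs <- planted_betas(3, 4, 8, margin = 3, sd = 1)
  cv1 <- cross_validate(bs)
  perm <- sample(nrow(bs$betas))
  bs2 <- beta_series(bs$betas[perm, ], bs$labels[perm, ])
  cv2 <- cross_validate(bs2)
  expect_equal(cv1$overall_accuracy, cv2$overall_accuracy)
  expect_equal(unclass(cv1$confusion), unclass(cv2$confusion))
})

test_that("a class missing from a training split is reported", {
  set.seed(33)
  bs <- null_betas(2, 3, 4)
  # remove every c2 sample outside run 1 -> folds testing run 2/3 keep c2,
  # but the fold holding out run 1 cannot train on... construct directly:
  keep <- !(bs$labels$condition == "c2" & bs$labels$run != 1)
  bs2 <- beta_series(bs$betas[keep, ], bs$labels[keep, ])
  expect_error(cross_validate(bs2), "class 'c2'")
})

test_that("accuracy_from_confusion is trace over total", {
  cm <- matrix(c(5, 0, 0, 7), 2)
  expect_equal(accuracy_from_confusion(cm), 1)
  cm2 <- matrix(c(0, 3, 4, 0), 2)
  expect_equal(accuracy_from_confusion(cm2), 0)
  set.seed(34)
  m <- matrix(rpois(16, 4), 4)
  hand <- (m[1, 1] + m[2, 2] + m[3, 3] + m[4, 4]) / sum(m)
  expect_equal(accuracy_from_confusion(m), hand)
  expect_error(accuracy_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("shuffled targets yield chance-level accuracy on average", {
  set.seed(35)
  accs <- replicate(40, {
    bs <- planted_betas(2, 4, 6, margin = 10)
    # shuffle targets independently of the data, within runs
    for (r in unique(bs$labels$run)) {
      idx <- which(bs$labels$run == r)
      bs$labels$condition[idx] <- sample(bs$labels$condition[idx])
    }
    cross_validate(bs, classifier = mean_classifier())$overall_accuracy
  })
  band <- chance_interval(0.5, 40 * 8)  # 8 test predictions per repetition
  expect_gt(mean(accs), band[1])
  expect_lt(mean(accs), band[2])
})

test_that("permutation test follows the add-one p formula and is seeded", {
  set.seed(36)
  bs <- planted_betas(2, 4, 6, margin = 15)
  pt <- permutation_test(bs, classifier = mean_classifier(),
                         n_permutations = 99L, seed = 7L)
  expect_equal(pt$observed, 1.0)
  b <- sum(pt$null_accuracies >= pt$observed)
  expect_equal(pt$p_value, (1 + b) / 100)
  if (b == 0) expect_equal(pt$p_value, 0.01)
  expect_true(all(pt$null_accuracies >= 0 & pt$null_accuracies <= 1))
  # observed equals the plain cross-validated accuracy
  expect_equal(pt$observed,
               cross_validate(bs,
                              classifier = mean_classifier())$overall_accuracy)
  # determinism from the seed
  pt2 <- permutation_test(bs, classifier = mean_classifier(),
                          n_permutations = 99L, seed = 7L)
  expect_identical(pt$null_accuracies, pt2$null_accuracies)
  pt3 <- permutation_test(bs, classifier = mean_classifier(),
                          n_permutations = 99L, seed = 8L)
  expect_false(identical(pt$null_accuracies, pt3$null_accuracies))
})

test_that("label permutations preserve per-run class counts", {
  set.seed(37)
  # unbalanced class counts per run make count preservation detectable
  labels <- data.frame(
    condition = c("a", "a", "b", "a", "b", "b", "a", "b", "a", "b", "a", "b"),
    run = rep(1:3, each = 4), trial = NA_integer_)
  bs <- beta_series(matrix(rnorm(12 * 5), 12), labels)
  orig_counts <- table(labels$run, labels$condition)
  # a spy classifier records every training label vector it sees
  seen <- list()
  spy <- structure(list(
    name = "spy",
    fit = function(x, y) { seen[[length(seen) + 1L]] <<- y; y },
    predict = function(model, x)
      rep(levels(model)[1], nrow(x))
  ), class = "mvpa_classifier")
  pt <- permutation_test(bs, classifier = spy, n_permutations = 5L,
                         seed = 1L)
  # each fold trains on 2 runs x 4 samples; permutation must keep the
  # total class counts of every training split (a-vs-b count per 2 runs)
  expect_true(all(vapply(seen, length, integer(1)) == 8L))
  # and the documented scheme preserves exact per-run counts
  for (i in 1:20) {
    perm <- labels$condition
    for (r in unique(labels$run)) {
      idx <- which(labels$run == r)
      perm[idx] <- perm[idx][sample(length(idx))]
    }
    expect_equal(table(labels$run, perm), orig_counts,
                 ignore_attr = TRUE)
  }
})
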