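#' Exhaustive leave-n-runs-out fold scheme
#'
#' Builds all `choose(n, n_test)` train/test partitions of the distinct run
#' identifiers, test sets in lexicographic order. `n_test = 1` is the
#' classic leave-one-run-out scheme.
#'
#' @param chunks vector of run identifiers (repeats allowed; distinct
#'   values are used).
#' @param n_test number of runs held out per fold (`1 <= n_test < n runs`).
#' @return An object of class `fold_scheme`: list of folds, each with
#'   `train` and `test` run-id vectors.
#' @examples
#' make_folds(1:4, n_test = 2)  # 6 folds
#' @export
make_folds <- function(chunks, n_test = 1L) {
  u <- sort(unique(chunks))
  n <- length(u)
  n_test <- as.integer(n_test)
  if (n < 2L) stop("cross-validation requires at least 2 distinct chunks")
  if (n_test < 1L || n_test >= n)
    stop("n_test must satisfy 1 <= n_test < ", n, " (got ", n_test, ")")
  combos <- utils::combn(u, n_test, simplify = FALSE)
  folds <- lapply(combos, function(te)
    list(train = setdiff(u, te), test = te))
  structure(list(folds = folds, chunks = u, n_test = n_test),
            class = "fold_scheme")
}

#' Linear support vector machine classifier
#'
#' The default classifier: a soft-margin linear SVM (cost `C = 1`,
#' one-vs-one multiclass voting), fitted on unscaled inputs so that the
#' pipeline's explicit normalization stages stay in control. Any object
#' implementing the same `fit(x, y)` / `predict(model, x)` contract can be
#' substituted.
#'
#' @param cost soft-margin cost parameter `C`.
#' @return An object of class `mvpa_classifier`.
#' @export
svm_classifier <- function(cost = 1) {
  structure(list(
    name = sprintf("linear SVM (C = %g)", cost),
    fit = function(x, y) {
      e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE,
                 type = "C-classification")
    },
    predict = function(model, x) as.character(stats::predict(model, x))
  ), class = "mvpa_classifier")
}

# Shared CV engine working on bare matrices; returns the pooled confusion
# counts (rows = predicted, cols = target) and per-fold accuracies.
cv_engine <- function(x, targets, chunks, folds, classifier, classes) {
  k <- length(classes)
  counts <- matrix(0L, k, k, dimnames = list(predicted = classes,
                                             target = classes))
  nf <- length(folds$folds)
  per_fold <- numeric(nf)
  yf <- factor(targets, levels = classes)
  for (fi in seq_len(nf)) {
    fold <- folds$folds[[fi]]
    tr <- chunks %in% fold$train
    te <- chunks %in% fold$test
    model <- classifier$fit(x[tr, , drop = FALSE], yf[tr])
    pred <- classifier$predict(model, x[te, , drop = FALSE])
    truth <- as.character(yf[te])
    for (i in seq_along(pred))
      counts[pred[i], truth[i]] <- counts[pred[i], truth[i]] + 1L
    per_fold[fi] <- mean(pred == truth)
  }
  list(counts = counts, per_fold = per_fold)
}

check_folds_cover <- function(targets, chunks, folds, classes) {
  for (fi in seq_along(folds$folds)) {
    tr <- chunks %in% folds$folds[[fi]]$train
    present <- unique(targets[tr])
    missing <- setdiff(classes, present)
    if (length(missing))
      stop("fold ", fi, ": class '", missing[1L],
           "' has no training samples")
  }
  invisible(TRUE)
}

#' Cross-validated classification of a beta series
#'
#' For each fold the classifier is trained on the training runs' betas and
#' evaluated on the held-out runs; predictions are pooled into a confusion
#' matrix (rows = predicted, columns = target). The procedure is
#' deterministic given fixed inputs.
#'
#' @param betas a [beta_series]; `labels$condition` are the targets and
#'   `labels$run` the chunks.
#' @param folds a `fold_scheme`; defaults to leave-one-run-out over the
#'   beta series' runs.
#' @param classifier an `mvpa_classifier`; defaults to [svm_classifier()].
#' @param classes optional ordered class labels; defaults to the beta
#'   series' condition order (user's list order when recorded, else
#'   sorted).
#' @return An object of class `cv_result`: `confusion` (class
#'   `confusion_matrix`), `overall_accuracy`, `per_fold_accuracy`,
#'   `chance_level`, `classifier`.
#' @export
cross_validate <- function(betas, folds = NULL,
                           classifier = svm_classifier(), classes = NULL) {
  stopifnot(inherits(betas, "beta_series"))
  targets <- as.character(betas$labels$condition)
  chunks <- betas$labels$run
  if (is.null(folds)) folds <- make_folds(chunks)
  if (is.null(classes))
    classes <- attr(betas, "condition_order") %||% sort(unique(targets))
  check_folds_cover(targets, chunks, folds, classes)
  res <- cv_engine(betas$betas, targets, chunks, folds, classifier, classes)
  confusion <- structure(res$counts, class = c("confusion_matrix", "matrix"))
  structure(list(confusion = confusion,
                 overall_accuracy = accuracy_from_confusion(confusion),
                 per_fold_accuracy = res$per_fold,
                 chance_level = 1 / length(classes),
                 classes = classes,
                 classifier = classifier$name,
                 folds = folds),
            class = "cv_result")
}

#' Overall accuracy from a confusion matrix
#'
#' @param confusion square count matrix, rows = predicted, cols = target.
#' @return `trace / total`, the fraction of correct predictions.
#' @export
accuracy_from_confusion <- function(confusion) {
  total <- sum(confusion)
  if (!length(confusion) || total == 0) stop("empty confusion matrix")
  sum(diag(as.matrix(confusion))) / total
}

#' Label-permutation significance test for cross-validated accuracy
#'
#' Builds an empirical null distribution by repeatedly permuting the
#' condition labels uniformly at random *within each run* (the run is the
#' exchangeability block, preserving per-run class counts and the folding
#' structure) and re-running the full cross-validation. The p-value uses
#' the add-one estimator \eqn{p = (1 + b) / (1 + N)} with
#' \eqn{b = \#\{null \ge observed\}}, which is never zero.
#'
#' @inheritParams cross_validate
#' @param n_permutations number of label permutations `N` (`>= 1`).
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @return An object of class `permutation_result`: `observed`,
#'   `null_accuracies`, `n_permutations`, `p_value`, `seed`, plus the
#'   unpermuted `cv` result.
#' @export
permutation_test <- function(betas, folds = NULL,
                             classifier = svm_classifier(),
                             n_permutations = 1000L, seed = 1L,
                             classes = NULL) {
  stopifnot(inherits(betas, "beta_series"), n_permutations >= 1L)
  targets <- as.character(betas$labels$condition)
  chunks <- betas$labels$run
  if (is.null(folds)) folds <- make_folds(chunks)
  if (is.null(classes))
    classes <- attr(betas, "condition_order") %||% sort(unique(targets))
  check_folds_cover(targets, chunks, folds, classes)
  cv <- cross_validate(betas, folds, classifier, classes)
  observed <- cv$overall_accuracy

  run_index <- split(seq_along(chunks), chunks)
  x <- betas$betas
  null_acc <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      perm <- targets
      for (idx in run_index) perm[idx] <- perm[idx][sample.int(length(idx))]
      res <- cv_engine(x, perm, chunks, folds, classifier, classes)
      sum(diag(res$counts)) / sum(res$counts)
    }, numeric(1))
  })
  b <- sum(null_acc >= observed - 1e-12)
  structure(list(observed = observed, null_accuracies = null_acc,
                 n_permutations = as.integer(n_permutations),
                 p_value = (1 + b) / (1 + n_permutations),
                 seed = as.integer(seed), cv = cv),
            class = "permutation_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validated classification: %d classes, %d folds\n",
              length(x$classes), length(x$per_fold_accuracy)))
  cat(sprintf("  overall accuracy %.2f%% (chance %.2f%%), classifier: %s\n",
              100 * x$overall_accuracy, 100 * x$chance_level, x$classifier))
  cat("Confusion matrix (rows = predicted, columns = target):\n")
  print(unclass(x$confusion))
  invisible(x)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("Permutation test: observed accuracy %.2f%%, ",
                     "N = %d permutations, p = %.5g\n"),
              100 * x$observed, x$n_permutations, x$p_value))
  invisible(x)
}
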