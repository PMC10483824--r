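#' Spherical searchlight neighborhood offsets
#'
#' All integer voxel offsets `(di, dj, dk)` with
#' `di^2 + dj^2 + dk^2 <= radius^2`. The set always contains the origin and
#' is closed under sign flips and axis permutations.
#'
#' @param radius sphere radius in voxel units (`>= 0`).
#' @return Integer matrix, offsets x 3, of class `sphere_offsets` with a
#'   `radius` attribute. Radius 1 yields 7 offsets; radius 2 yields 33.
#' @export
sphere_offsets <- function(radius) {
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("searchlight radius must be a single non-negative number")
  m <- floor(radius)
  g <- expand.grid(di = -m:m, dj = -m:m, dk = -m:m)
  keep <- g$di^2 + g$dj^2 + g$dk^2 <= radius^2 + 1e-9
  off <- as.matrix(g[keep, , drop = FALSE])
  storage.mode(off) <- "integer"
  rownames(off) <- NULL
  structure(off, radius = radius, class = c("sphere_offsets", "matrix"))
}

#' Accuracy map container
#'
#' A 3D grid of classification accuracies aligned to the functional grid;
#' voxels that were not evaluated hold the fill value (`NA`, stored as NaN
#' in NIfTI output).
#'
#' @param values 3D numeric array.
#' @param affine 4x4 voxel-to-world matrix (may be `NULL` for toy grids).
#' @return An object of class `accuracy_map`.
#' @export
accuracy_map <- function(values, affine = NULL) {
  if (length(dim(values)) == 4L && dim(values)[4L] == 1L)
    dim(values) <- dim(values)[1:3]
  if (length(dim(values)) != 3L) stop("accuracy map values must be 3D")
  if (!is.null(affine)) affine <- as_affine(affine)
  structure(list(values = values, affine = affine),
            class = "accuracy_map")
}

#' @export
print.accuracy_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("Accuracy map: grid %s, %d voxels evaluated",
              paste(dim(x$values), collapse = "x"), length(v)))
  if (length(v))
    cat(sprintf(", accuracy range [%.3f, %.3f], mean %.3f", min(v), max(v),
                mean(v)))
  cat("\n")
  invisible(x)
}

#' Whole-brain volumetric searchlight classification
#'
#' For every in-mask voxel, the cross-validated classification accuracy of
#' the sphere of features centered at that voxel (clipped to the mask and
#' to the volume bounds) is written into a 3D accuracy map. Centers with
#' fewer than `min_features` available features receive the fill value,
#' distinguishing "not evaluated" from "evaluated at chance". Centers are
#' independent; results do not depend on evaluation order.
#'
#' @param betas a [beta_series] on whole-brain features whose
#'   `feature_coords` cover the mask's nonzero voxels.
#' @param mask a [mask_volume] defining the candidate centers.
#' @param radius sphere radius in voxel units. Use [mm_to_voxels()] to
#'   convert a millimeter radius via the affine.
#' @param folds,classifier,classes as in [cross_validate()].
#' @param min_features minimum sphere size to evaluate (default 2).
#' @param fill value for unevaluated voxels.
#' @return An [accuracy_map].
#' @export
run_searchlight <- function(betas, mask, radius = 2, folds = NULL,
                            classifier = svm_classifier(), classes = NULL,
                            min_features = 2L, fill = NA_real_) {
  stopifnot(inherits(betas, "beta_series"), inherits(mask, "mask_volume"))
  gd <- dim(mask$data)
  if (!any(mask$data != 0)) stop("searchlight mask is empty")
  co <- betas$feature_coords
  if (is.null(co)) stop("beta series has no feature coordinates")
  targets <- as.character(betas$labels$condition)
  chunks <- betas$labels$run
  if (is.null(folds)) folds <- make_folds(chunks)
  if (is.null(classes))
    classes <- attr(betas, "condition_order") %||% sort(unique(targets))
  check_folds_cover(targets, chunks, folds, classes)

  # feature index per voxel (0 where no feature), column-major linear index
  feat_idx <- integer(prod(gd))
  lin_feat <- 1L + co[, 1L] + gd[1L] * (co[, 2L] + gd[2L] * co[, 3L])
  feat_idx[lin_feat] <- seq_len(nrow(co))
  in_mask <- as.vector(mask$data != 0)
  centers <- which(in_mask & feat_idx > 0L)
  if (!length(centers))
    stop("no in-mask voxel is covered by the beta series' features")
  mask_feat <- feat_idx
  mask_feat[!in_mask] <- 0L
  off <- sphere_offsets(radius)
  x <- betas$betas

  values <- array(fill, dim = gd)
  cidx <- arrayInd(centers, gd)
  for (ci in seq_along(centers)) {
    ctr <- cidx[ci, ]
    nb <- sweep(off, 2L, as.integer(ctr), "+")
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= gd[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= gd[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= gd[3L]
    nb <- nb[ok, , drop = FALSE]
    f <- mask_feat[nb[, 1L] + gd[1L] * (nb[, 2L] - 1L) +
                     gd[1L] * gd[2L] * (nb[, 3L] - 1L)]
    f <- f[f > 0L]
    if (length(f) < min_features) next
    res <- cv_engine(x[, f, drop = FALSE], targets, chunks, folds,
                     classifier, classes)
    values[centers[ci]] <- sum(diag(res$counts)) / sum(res$counts)
  }
  accuracy_map(values, betas$affine %||% mask$affine)
}

#' Convert a millimeter radius to voxel units via an affine
#'
#' Uses the mean voxel edge length of the affine's spatial columns.
#'
#' @param radius_mm radius in millimeters.
#' @param affine 4x4 voxel-to-world matrix.
#' @return Radius in voxel units.
#' @export
mm_to_voxels <- function(radius_mm, affine) {
  affine <- as_affine(affine)
  sizes <- sqrt(colSums(affine[1:3, 1:3]^2))
  radius_mm / mean(sizes)
}

#' Average accuracy maps across subjects
#'
#' Voxelwise mean ignoring fill values; voxels unfilled in every input stay
#' at the fill value.
#'
#' @param maps list of [accuracy_map]s on identical grids.
#' @return An [accuracy_map].
#' @export
average_maps <- function(maps) {
  if (!length(maps)) stop("average_maps needs at least one map")
  stopifnot(all(vapply(maps, inherits, logical(1), "accuracy_map")))
  gd <- dim(maps[[1L]]$values)
  for (m in maps) {
    if (!identical(dim(m$values), gd))
      stop("accuracy maps have mismatched grids")
  }
  stack <- vapply(maps, function(m) as.vector(m$values),
                  numeric(prod(gd)))
  stack <- matrix(stack, nrow = prod(gd))
  mean_v <- rowMeans(stack, na.rm = TRUE)
  mean_v[!is.finite(mean_v)] <- NA_real_
  accuracy_map(array(mean_v, dim = gd), maps[[1L]]$affine)
}
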