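#' Volumetric functional runs, masks and sample matrices
#'
#' @description
#' `bold_run()` wraps one run's 4D data grid with its affine and repetition
#' time. `mask_volume()` wraps a binary 3D region-of-interest grid.
#' `mvpa_dataset()` is the samples-by-features currency that flows between
#' all later stages: one row per volume (or per beta), one column per voxel
#' or vertex, with per-sample `chunks` (run identifiers) and optional
#' `targets`.
#'
#' @param data 4D numeric array (`nx x ny x nz x nt`) for `bold_run`; 3D
#'   binary array for `mask_volume`.
#' @param affine invertible 4x4 voxel-to-world matrix.
#' @param tr repetition time in seconds (`> 0`).
#' @param run_id,subject,task,session entity labels.
#' @return `bold_run`/`mask_volume`/`mvpa_dataset` objects.
#' @name volumes
NULL

#' @rdname volumes
#' @export
bold_run <- function(data, affine, tr, run_id = NA_integer_,
                     subject = NA_character_, task = NA_character_,
                     session = NULL) {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("bold data must be a 4D array")
  if (dim(data)[4L] < 1L) stop("bold run must contain at least one volume")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a positive number of seconds")
  affine <- as_affine(affine)
  structure(list(data = data, affine = affine, tr = as.numeric(tr),
                 run_id = as.integer(run_id), subject = subject,
                 task = task, session = session),
            class = "bold_run")
}

as_affine <- function(affine) {
  affine <- matrix(as.numeric(affine), 4L, 4L)
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps * 100)
    stop("affine must be an invertible 4x4 matrix")
  affine
}

#' @rdname volumes
#' @param name mask label, e.g. `"VT"`.
#' @export
mask_volume <- function(data, affine = NULL, name = "mask") {
  data <- unclass(data)
  attributes(data) <- list(dim = dim(data))
  if (length(dim(data)) != 3L) stop("mask must be a 3D array")
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be binary (0/1); found other values")
  if (!is.null(affine)) affine <- as_affine(affine)
  structure(list(data = data, affine = affine, name = name),
            class = "mask_volume")
}

#' Read a 4D functional NIfTI run
#'
#' The repetition time is taken from the BIDS JSON sidecar
#' (`RepetitionTime`, the authoritative source) when one exists next to the
#' image, falling back to the NIfTI header's `pixdim[4]`. When both exist
#' and disagree by more than 1 ms a warning is raised and the sidecar wins.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param sidecar optional explicit path to the JSON sidecar.
#' @inheritParams volumes
#' @return A [bold_run].
#' @export
load_bold_run <- function(path, sidecar = NULL, run_id = NA_integer_,
                          subject = NA_character_, task = NA_character_,
                          session = NULL) {
  if (!file.exists(path)) stop("functional image not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  tr_hdr <- RNifti::pixdim(img)[4L]
  if (is.null(sidecar)) {
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  }
  tr <- NA_real_
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$RepetitionTime)) tr <- as.numeric(meta$RepetitionTime)
  }
  if (is.na(tr)) {
    tr <- tr_hdr
  } else if (is.finite(tr_hdr) && tr_hdr > 0 && abs(tr - tr_hdr) > 1e-3) {
    warning(sprintf(
      "RepetitionTime mismatch for %s: sidecar %.4f s vs header %.4f s; using sidecar",
      path, tr, tr_hdr))
  }
  if (!is.finite(tr) || tr <= 0)
    stop("could not determine a positive repetition time for ", path)
  bold_run(arr, affine, tr, run_id = run_id, subject = subject,
           task = task, session = session)
}

#' Read a binary ROI mask volume
#'
#' Values are binarized at `> 0.5` to absorb floating-point storage of 0/1
#' masks; genuinely non-binary volumes are rejected.
#'
#' @param path path to a `.nii`/`.nii.gz` mask.
#' @param name mask label; defaults to the file stem.
#' @return A [mask_volume].
#' @export
load_mask <- function(path, name = NULL) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4L] == 1L) dim(arr) <- dim(arr)[1:3]
  u <- unique(round(as.vector(arr), 6))
  if (!all(u %in% c(0, 1)))
    stop("mask ", path, " is not binary (values other than 0/1 present)")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  if (is.null(name))
    name <- sub("\\.nii(\\.gz)?$", "", basename(path))
  mask_volume((arr > 0.5) + 0, affine, name = name)
}

#' Concatenate functional runs along time
#'
#' Runs are stacked in ascending `run_id` order into one 4D grid; a `chunks`
#' vector labels every volume with its source run. All runs must share grid
#' shape, repetition time, and affine (element-wise tolerance 1e-4).
#'
#' @param runs list of [bold_run] objects (at least one).
#' @return A list of class `bold_concat` with elements `data` (4D array),
#'   `chunks` (integer per volume), `affine`, `tr`.
#' @export
concatenate_runs <- function(runs) {
  if (!length(runs)) stop("concatenate_runs needs at least one run")
  stopifnot(all(vapply(runs, inherits, logical(1), "bold_run")))
  ids <- vapply(runs, function(r) r$run_id, integer(1))
  if (anyNA(ids)) ids <- seq_along(runs) - 1L
  runs <- runs[order(ids)]
  ids <- sort(ids)
  ref <- runs[[1L]]
  ref_dim <- dim(ref$data)[1:3]
  for (i in seq_along(runs)) {
    r <- runs[[i]]
    if (!identical(dim(r$data)[1:3], ref_dim))
      stop("run ", ids[i], " grid shape (", paste(dim(r$data)[1:3], collapse = "x"),
           ") differs from run ", ids[1L], " (", paste(ref_dim, collapse = "x"), ")")
    if (abs(r$tr - ref$tr) > 1e-4)
      stop("run ", ids[i], " repetition time ", r$tr,
           " differs from run ", ids[1L], " (", ref$tr, ")")
    if (max(abs(r$affine - ref$affine)) > 1e-4)
      stop("run ", ids[i], " affine differs from run ", ids[1L],
           " beyond tolerance 1e-4")
  }
  nts <- vapply(runs, function(r) dim(r$data)[4L], integer(1))
  total <- sum(nts)
  out <- array(0, dim = c(ref_dim, total))
  chunks <- integer(total)
  at <- 0L
  for (i in seq_along(runs)) {
    idx <- at + seq_len(nts[i])
    out[, , , idx] <- runs[[i]]$data
    chunks[idx] <- ids[i]
    at <- at + nts[i]
  }
  structure(list(data = out, chunks = chunks, affine = ref$affine,
                 tr = ref$tr),
            class = "bold_concat")
}

#' @rdname volumes
#' @param samples numeric matrix, samples x features.
#' @param targets optional per-sample labels.
#' @param chunks per-sample run identifiers.
#' @param feature_coords integer matrix (features x 3) of 0-based voxel
#'   indices, or a vector of vertex indices for surface data.
#' @param grid_dim 3-element grid dimensions for volumetric data.
#' @export
mvpa_dataset <- function(samples, chunks, targets = NULL,
                         feature_coords = NULL, affine = NULL,
                         tr = NA_real_, grid_dim = NULL) {
  samples <- as.matrix(samples)
  if (length(chunks) != nrow(samples))
    stop("chunks length must equal the number of samples")
  if (!is.null(targets) && length(targets) != nrow(samples))
    stop("targets length must equal the number of samples")
  if (!is.null(feature_coords)) {
    if (is.matrix(feature_coords) && nrow(feature_coords) != ncol(samples))
      stop("feature_coords must have one row per feature")
  }
  structure(list(samples = samples, chunks = as.integer(chunks),
                 targets = targets, feature_coords = feature_coords,
                 affine = affine, tr = as.numeric(tr), grid_dim = grid_dim),
            class = "mvpa_dataset")
}

#' Extract a masked samples-by-features matrix
#'
#' Turns a 4D grid (a [bold_run], the result of [concatenate_runs()], or a
#' plain 4D array) into an [mvpa_dataset]. With a mask, one feature is
#' created per nonzero mask voxel; without one, every voxel becomes a
#' feature (whole-brain / searchlight mode). Features are ordered by
#' row-major scan over 0-based voxel indices `(i, j, k)` — `k` fastest — a
#' fixed convention so that accuracy/weight maps can be written back to the
#' grid reproducibly.
#'
#' @param x a `bold_run`, `bold_concat`, or 4D array.
#' @param mask optional [mask_volume] on the same grid.
#' @param chunks per-volume run labels; taken from `x` when it carries them.
#' @param affine,tr used when `x` is a bare array.
#' @return An [mvpa_dataset] with `feature_coords` giving the 0-based
#'   `(i, j, k)` index of every feature.
#' @export
apply_mask <- function(x, mask = NULL, chunks = NULL, affine = NULL,
                       tr = NA_real_) {
  if (inherits(x, "bold_run")) {
    data <- x$data; affine <- x$affine; tr <- x$tr
    if (is.null(chunks)) chunks <- rep(x$run_id, dim(data)[4L])
  } else if (inherits(x, "bold_concat")) {
    data <- x$data; affine <- x$affine; tr <- x$tr
    if (is.null(chunks)) chunks <- x$chunks
  } else {
    data <- x
    if (length(dim(data)) != 4L) stop("x must be a 4D array")
    if (is.null(chunks)) chunks <- rep(0L, dim(data)[4L])
  }
  gd <- dim(data)[1:3]
  nt <- dim(data)[4L]
  if (is.null(mask)) {
    keep <- array(TRUE, dim = gd)
  } else {
    stopifnot(inherits(mask, "mask_volume"))
    if (!identical(dim(mask$data), gd))
      stop("mask grid (", paste(dim(mask$data), collapse = "x"),
           ") does not match functional grid (", paste(gd, collapse = "x"), ")")
    keep <- mask$data != 0
    if (!any(keep)) stop("mask '", mask$name, "' selects no voxels (empty ROI)")
  }
  lin <- which(keep)
  co <- arrayInd(lin, gd) - 1L            # 0-based (i, j, k)
  ord <- order(co[, 1L], co[, 2L], co[, 3L])  # row-major: i major, k fastest
  lin <- lin[ord]
  co <- co[ord, , drop = FALSE]
  flat <- matrix(data, nrow = prod(gd), ncol = nt)
  samples <- t(flat[lin, , drop = FALSE])
  colnames(co) <- c("i", "j", "k")
  mvpa_dataset(samples, chunks = chunks, feature_coords = co,
               affine = affine, tr = tr, grid_dim = gd)
}

#' @export
print.mvpa_dataset <- function(x, ...) {
  cat(sprintf("MVPA dataset: %d samples x %d features, %d chunk(s)\n",
              nrow(x$samples), ncol(x$samples), length(unique(x$chunks))))
  invisible(x)
}

#' Write a 3D/4D volume to NIfTI
#'
#' Used for accuracy maps and beta/weight patterns. Output is gzip
#' compressed when `path` ends in `.nii.gz`. `NA`/`NaN` fill values survive
#' the round trip (stored as NaN).
#'
#' @param map an `accuracy_map`, or a numeric array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param affine 4x4 affine; required when `map` is a bare array.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, affine = NULL) {
  if (inherits(map, "accuracy_map")) {
    values <- map$values
    affine <- affine %||% map$affine
  } else {
    values <- map
  }
  if (is.null(affine)) stop("an affine is required to write a NIfTI map")
  if (is.null(dim(values))) stop("map values must be an array with a grid")
  affine <- as_affine(affine)
  img <- RNifti::asNifti(values)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume written by [write_map()]
#'
#' @param path NIfTI path.
#' @return An `accuracy_map` (values + affine).
#' @export
read_map <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  accuracy_map(as.array(img), affine)
}
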