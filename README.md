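# mvpadecode

Multivariate pattern analysis (MVPA) of task fMRI data organized in
BIDS-style directories, for researchers who want to go from per-run 4D
images and `events.tsv` timing tables to cross-validated decoding results
without writing glue code. The package covers the full pipeline:

1. **Input** — per-run volumetric NIfTI (`.nii`/`.nii.gz`) with the
   repetition time taken from the JSON sidecar (`RepetitionTime`) or the
   header, BIDS `events.tsv` tables (`onset`, `duration`, `trial_type`),
   optional binary ROI masks, and GIfTI surface time series for ROI-mode
   analyses. Runs are concatenated per subject in a *participant prep*
   phase.
2. **Normalization** — optional run-wise polynomial detrending and
   z-scoring of each voxel's time series within run, and a second
   z-scoring of the estimated betas across runs.
3. **Beta-series GLM** — boxcar regressors built from the event timing are
   convolved with a canonical double-gamma hemodynamic response function
   h(t) = g(t; δ₁/σ₁, σ₁) − r·g(t; δ₂/σ₂, σ₂) (peak-normalized), and a
   fixed-effects GLM is fitted per run by ordinary least squares, giving
   betas per condition per run, per trial (LSA), or by the
   least-squares-single (LSS) procedure in which each trial gets its own
   GLM with one single-trial regressor plus per-condition regressors for
   all remaining trials.
4. **Decoding** — leave-n-runs-out cross-validation (all C(n, k) folds) of
   a linear soft-margin SVM (C = 1) on the beta patterns, pooled into a
   confusion matrix (rows = predicted, columns = target) with overall
   accuracy ACC = trace/total, plus label-permutation significance
   testing: labels are permuted within each run, the full cross-validation
   is re-run N times, and p = (1 + #{null ≥ observed}) / (1 + N).
5. **RSA** — representational dissimilarity matrices between all beta
   patterns under correlation distance d = 1 − r (range 0–2), Euclidean
   distance, or Mahalanobis distance with a Ledoit–Wolf
   shrinkage-regularized covariance; written as TSV.
6. **Searchlight** — whole-brain volumetric searchlight: the
   cross-validated accuracy of the sphere of voxels (radius in voxel
   units) around every in-mask voxel, written as a NIfTI accuracy map;
   subject maps can be averaged.
7. **Reporting** — a self-contained HTML report per subject (confusion
   matrix, accuracy and chance level, permutation p, RDM heat map, or map
   summary), TSV exports of per-fold accuracies and design matrices.

A synthetic-data generator (`synthetic_spec()`, `generate_dataset()`)
writes BIDS-style trees with known planted condition patterns so every
stage is testable end to end without downloads; `haxby_like_spec()` is a
preset mirroring the classic 8-category × 12-run object-viewing block
design.

## Worked example

Generate a synthetic 8-condition, 12-run blocked dataset with a planted
multivariate code, run both pipeline phases, and decode within the
planted ROI:

```r
library(mvpadecode)

spec <- haxby_like_spec(effect_amplitude = 5, seed = 20L)
bids <- tempfile("bids"); out <- tempfile("out")
generate_dataset(spec, bids)

run_participant_prep(run_config(bids, out, "participant_prep",
                                task = "objectviewing"))
write_map(informative_mask(spec)$data, file.path(out, "masks", "VT.nii.gz"),
          affine = diag(c(3, 3, 3, 1)))

res <- run_participant_test(run_config(
  bids, out, "participant_test", task = "objectviewing",
  mask = "VT", bzscore = TRUE,
  conditions_to_classify = spec$conditions,
  n_permutations = 99L, seed = 1L))
print(res[["01"]]$cv)
print(res[["01"]]$perm)
```

This prints (abridged):

```
Cross-validated classification: 8 classes, 12 folds
  overall accuracy 100.00% (chance 12.50%), classifier: linear SVM (C = 1)
Confusion matrix (rows = predicted, columns = target):
              target
predicted      bottle cat chair face house scissors scrambledpix shoe
  bottle           12   0     0    0     0        0            0    0
  ...
Permutation test: observed accuracy 100.00%, N = 99 permutations, p = 0.01
```

With an amplitude-to-noise ratio of 5 the planted patterns are fully
separable, so every one of the 96 held-out betas (8 conditions × 12
runs) is classified correctly; the permutation p-value takes its
smallest attainable value (1 + 0)/(1 + 99) = 0.01. An HTML report with
the confusion table is written under `out/sub-01/`.

The same configuration drives the command-line interface:

```sh
Rscript inst/cli/mvpa-decode.R <bids_dir> <output_dir> participant_prep \
    --task objectviewing
Rscript inst/cli/mvpa-decode.R <bids_dir> <output_dir> participant_test \
    --task objectviewing --mask VT --bzscore \
    --conditions_to_classify bottle cat chair face house scissors scrambledpix shoe
```

Use `--rsa` for an RDM instead of classification, or `--searchlight 2.0`
for a whole-brain accuracy map.

## Scope notes

Preprocessing (motion correction, registration, fMRIPrep derivatives) is
out of scope: the package consumes already-preprocessed, space-aligned
images. Surface-based (geodesic-disc) searchlights, prewhitening/AR noise
models, and cluster-level inference are not implemented; see the methods
vignette (`vignettes/mvpa-pipeline.Rmd`) for the full list of assumptions
and design choices.
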