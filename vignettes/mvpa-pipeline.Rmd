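---
title: "Beta-series MVPA: models, assumptions and design choices"
author: "mvpadecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-series MVPA: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpadecode)
```

This vignette documents the statistical model behind the pipeline, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design decisions that were genuinely
open.

## The model

Decoding operates on *beta series*: GLM amplitude estimates, one pattern
per condition (or trial) per run, rather than on raw volumes. For each
run the BOLD signal at voxel $v$ is modeled as

$$ y_v(t) = \sum_j \beta_{jv} \, (b_j * h)(t) + \text{drift} + \varepsilon $$

where $b_j$ is the boxcar of regressor $j$ (1 during each of its events,
0 elsewhere), $h$ the hemodynamic response function, and the drift a
Legendre polynomial basis plus intercept. Ordinary least squares gives
$\hat\beta$; rank-deficient designs fall back to the minimum-norm
solution with a prominent warning rather than failing, because collinear
toy designs are common in exploratory use and the warning keeps the
misuse visible.

**HRF.** The canonical double-gamma: gamma-density peak minus a scaled
gamma-density undershoot, parameterized by peak delay (6 s), undershoot
delay (16 s), dispersions (1 s each) and undershoot ratio (1/6), all
configurable through `hrf_spec()`. These are the field-standard defaults;
the response maximum then falls near 5 s and the curve is scaled so its
dense-grid maximum is exactly 1. Regressors are built on a grid
oversampled 16× relative to the repetition time, discretely convolved
with the HRF on that grid (scaled by the grid step, so the result
approximates the continuous convolution and is insensitive to the
oversampling factor), and read off at scan onsets $t = i \cdot TR$. No
slice-timing offset is applied — slice-time alignment is a preprocessing
concern upstream of this package.

**Estimation modes.** *Per condition per run* (the default, suited to
blocked designs, variance-minimal), *per trial* (LSA: every event its own
regressor, more samples but more collinearity), and *LSS*: each trial in
turn gets a dedicated GLM holding one single-trial regressor plus
per-condition regressors aggregating all remaining trials, and only that
trial's beta is kept. LSS trades a little bias for much lower variance
when trials overlap. The GLM is fitted independently within each run,
with its own intercept and drift columns; this matches the
per-condition-per-run semantics, keeps runs exchangeable for
cross-validation, and resolves an ambiguity in the LSS formulation (the
"remaining trials" regressors are per condition *within the run*, an
interpretation this package fixes deliberately). Conditions outside the
user's classification list are retained as regressors of no interest —
dropping their events entirely would bias the betas of interest — and
their estimates are discarded after fitting.

**Normalization.** The fixed pipeline order is detrend → time-series
z-scoring → GLM → beta z-scoring, each stage independently switchable.
Z-scoring uses the population standard deviation (divisor $n$): the
choice is immaterial downstream but must be pinned for reproducibility.
Constant features are zeroed, not dropped, so feature indices stay
aligned with the mask for map writing. Beta z-scoring across runs is
generally recommended before RSA; for classification its benefit depends
on the classifier, which is why it is a flag and never implicit.

**Decoding.** Leave-$k$-runs-out cross-validation enumerates all
$\binom{n}{k}$ train/test partitions (default $k = 1$). The classifier is
a linear soft-margin SVM with $C = 1$ and one-vs-one multiclass voting —
the common library default, chosen because no hyperparameters are
dictated by the method itself — fitted on unscaled inputs so the explicit
normalization stages stay in control. The classifier is a pluggable
`fit`/`predict` contract, so any deterministic substitute can be used.
Significance is assessed by permuting condition labels *within each run*:
the run is the exchangeability block, so permutations preserve per-run
class counts and the folding structure. The p-value uses the add-one
estimator $p = (1+b)/(1+N)$, $b = \#\{\text{null} \ge \text{observed}\}$,
which is never zero and has granularity $1/(N{+}1)$ — with $N$
permutations no smaller p-value can honestly be reported.

**RSA.** Correlation distance $1 - r$ (0 = identical up to positive
affine transform, 2 = anti-correlated), Euclidean, or Mahalanobis.
Because beta counts are far smaller than voxel counts, the sample
covariance is singular; the Mahalanobis metric therefore uses Ledoit–Wolf
analytic shrinkage toward a scaled identity, the standard fix when
$n \ll p$. RDM rows are ordered condition-major (user's condition order,
else sorted), runs within condition.

**Searchlight.** For every in-mask voxel, the features inside the sphere
of integer offsets with $\|d\|_2 \le$ radius (voxel units; a helper
converts millimeters via the affine) — intersected with the mask and the
volume bounds, never padded — are cross-validated and the accuracy is
written at the center. Centers with fewer than `min_features` (default 2)
available features get the NaN fill value rather than chance, so "not
evaluated" is distinguishable from "evaluated at chance". Centers are
independent; results are identical under any evaluation order. Group maps
are voxelwise means ignoring fill values.

## The synthetic-data generator

`generate_dataset()` emulates exactly the input contract the pipeline
consumes: `sub-XX/func/` trees with gzipped 4D NIfTI, `events.tsv` and
JSON sidecars. The signal model plants, for each condition, a fixed
random Gaussian weight pattern over a ball of informative voxels; each
voxel's time series is amplitude × weight × (boxcar ∗ HRF) summed over
events, plus an optional linear drift and i.i.d. Gaussian noise. The
event schedule is blocked with constant inter-trial interval, block order
permuted per run from the seed, which guarantees balanced folds.
Defaults: one subject, TR 2.5 s, 9 s blocks, 6 s inter-trial interval,
12 s lead-in, 3 mm isotropic grid, noise SD 1. The `haxby_like_spec()`
preset fixes 8 conditions × 12 runs (one block per condition per run)
with amplitude-to-noise 5, the regime in which the planted patterns are
reliably decodable.

What the generator does **not** emulate: temporally autocorrelated
physiological noise (an optional AR(1) coefficient exists for robustness
checks, but the default is white, matching the GLM's no-prewhitening
assumption), motion, spatial smoothness, and surface geometry. Passing
tests on synthetic data therefore validates the *computational*
contracts — estimation, folding, permutation calibration, localization —
not robustness to real-data artifacts.

## Numerical choices and problem sizes

- OLS is solved by SVD pseudoinverse (tolerance $10^{-8}$ relative to the
  largest singular value), giving the minimum-norm solution under rank
  deficiency.
- Design rank is checked by singular values at the same tolerance; a
  deficient design carries a warning, not an error.
- The HRF convolution kernel is truncated at 32 s, past the undershoot's
  support at the default parameters.
- Permutation ties are counted conservatively (null ≥ observed within
  $10^{-12}$ counts against the hypothesis).
- The Mahalanobis covariance receives a $10^{-10}$-scaled ridge so the
  Cholesky factorization cannot fail on degenerate inputs.
- Test problem sizes were chosen as the smallest instances that exercise
  each contract meaningfully: grids of $6^3$–$12^3$ voxels, 4–12 runs,
  permutation calibration over 100 null datasets × 200 permutations, and
  a 2000-iteration null for the chance-level estimates in
  `scripts/acceptance.R`. In the searchlight localization test the
  planted amplitude-to-noise ratio is deliberately low (1 : 12 per voxel)
  so the accuracy map has a unique, localized peak: at high
  signal-to-noise, binary accuracy over 16 held-out betas saturates at
  1.0 across a plateau of spheres and the argmax is ill-defined.

## Known limitations

- No prewhitening or AR noise modeling in the GLM; with strongly
  autocorrelated noise the per-trial estimates are noisier than a GLS
  fit would give.
- Volumetric searchlight only; surface (geodesic-disc) neighborhoods are
  out of scope, though GIfTI ROI data can be read and decoded.
- Non-steady-state (dummy) volumes are never trimmed before
  concatenation; if present they should be removed upstream or absorbed
  by detrending.
- The confusion matrix convention is rows = predicted, columns = target;
  transposed conventions exist in the wild, so column sums (not row
  sums) equal the per-class test counts here.
- Radius units for the searchlight are voxels by default; a millimeter
  radius must be converted explicitly (`mm_to_voxels()`) because the
  affine, not the package, defines the voxel size.
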