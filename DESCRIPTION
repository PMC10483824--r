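Package: mvpadecode
Title: Multivariate Pattern Analysis of BIDS-Organized fMRI Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for multivariate pattern analysis (MVPA) of
    task fMRI data organized in BIDS-style directories. Reads per-run
    4D NIfTI volumes, BIDS events.tsv timing tables and region-of-interest
    masks; builds hemodynamic-response-convolved design matrices and
    estimates beta series by ordinary least squares (per condition or per
    trial) or by the least-squares-single (LSS) procedure; normalizes time
    series and betas by run-wise z-scoring and polynomial detrending;
    performs leave-n-runs-out cross-validated classification with a linear
    support vector machine, label-permutation significance testing,
    representational similarity analysis under correlation, Euclidean or
    shrinkage-Mahalanobis distances, and whole-brain volumetric searchlight
    accuracy mapping. Includes a synthetic BIDS dataset generator with
    planted multivariate patterns for validation, HTML reporting, and a
    two-phase command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    e1071,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
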