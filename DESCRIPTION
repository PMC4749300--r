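Package: stmorph
Title: ST-Segment Morphology Delineation of Ambulatory ECG Using
    Orthogonal Transformations
Version: 0.1.0
Authors@R:
    person("ST-Morphology", "Maintainers", email = "stmorph@example.org",
           role = c("aut", "cre"))
Description: Delineation of transient ST-segment morphology changes in
    long-term ambulatory electrocardiograms using orthogonal
    transformations.  Builds discrete orthonormal Legendre-polynomial
    (LPT) ST-segment basis functions by weighted modified Gram-Schmidt,
    and data-driven Karhunen-Loeve (KLT) basis functions from a robust
    covariance matrix of interval-class mean pattern vectors.  Provides
    an ECG preprocessing chain (zero-phase Butterworth low-pass,
    PQ-interval isoelectric estimation, cubic-spline baseline removal,
    abnormal-beat exclusion), per-beat diagnostic (heart rate, ST level,
    ST slope) and morphologic (KLT/LPT coefficient, residual-error,
    Mahalanobis-distance) feature-vector time series, a seeded synthetic
    ambulatory ECG generator with parameterized ST morphology and
    transient episodes, and an episode-classification harness
    (ischaemic versus heart-rate-related non-ischaemic) with five
    classifiers under repeated stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
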