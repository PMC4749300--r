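---
title: "Methods: orthogonal-transformation delineation of ST-segment morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthogonal-transformation delineation of ST-segment morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmorph)
```

## The model

`stmorph` treats the ST segment of each heartbeat as an M = 32-dimensional
pattern vector **x**(i, j): the isoelectric-corrected signal of lead i,
beat j, resampled onto 32 equally spaced points of the window from
F + 40 ms to F + 160 ms, where F is the per-beat stable fiducial point.
Two orthonormal 32 × 32 bases expand this vector:

* the **LPT** basis: discretized Legendre polynomials, obtained by
  weighted Gram–Schmidt orthonormalization of the monomials
  Q_(j−1)(x) = x^(j−1) sampled at x_i = 2(i−1)/(M−1) − 1 (both endpoints
  included, unit weights).  Column k is the discrete orthonormal polynomial
  of degree k − 1, so the first three columns are a constant, a line and a
  quadratic — the shapes of ST elevation/depression, ST slope and ST
  scooping.
* the **KLT** basis: eigenvectors of a robust covariance matrix in
  descending eigenvalue order.  The covariance is built from annotated
  interval classes of pattern vectors (ischaemic deviation, non-ischaemic
  deviation, no deviation, with leads pooled): each class is replaced by its
  mean, the class means are centralized by their unweighted grand mean, and
  the average outer product is taken.  Working on interval means rather than
  raw beats is what makes the estimate robust to beat-level noise.

Diagnostic features per beat are the instantaneous heart rate
h(j) = 60000 / RR(j) (h(1) backfilled from h(2)), the ST level
s_l = a_80(60) − z and the ST slope s_s = a_80(60) − a_20, where z is the
isoelectric level and a_80(60) is the amplitude at the rate-adjusted
measurement point: F + 160 ms for h ≤ 100 bpm, F + 120 ms for h ≥ 120 bpm,
linear in between; a_20 is read at F + 60 ms.  Morphologic features are the
first N = 9 projections s′ = Φᵀx, their variance-normalized versions
s_k = s′_k / ρ_k (KLT) or s′_k / θ_k (LPT), the RMS residual of the
9-coefficient reconstruction, and the compound distance
d(i, j) = sqrt(Σ_{k ≤ N_D} (s_k(i,j) − s_k(i,1))²), a Mahalanobis distance
because the normalized coefficients have unit training variance.

Assumptions: beats arrive with fiducial points and normal/abnormal labels
(from annotations or the generator; beat detection itself is out of scope);
the PQ interval is the correct isoelectric reference; 120 ms of ST window
are meaningfully sampled at the recorder's rate (250 Hz by default).

## Preprocessing

1. **Low-pass filtering.** A 6-pole Butterworth with −3 dB at 55 Hz,
   designed by the standard bilinear transform and applied
   forward-backward.  Zero-phase filtering is not part of the original
   single-pass description, but it preserves ST timing relative to F; the
   effective magnitude is the squared single-pass response, which only
   strengthens the stop band.  The designed coefficients agree with
   reference implementations to machine precision.
2. **Isoelectric level.** A 20 ms window slides over [F − 120, F − 20] ms;
   flatness is the sum of absolute first differences; z is the mean of the
   flattest window, ties resolved toward F.  The search constants are
   configurable defaults, not published values.
3. **Baseline removal.** A natural cubic spline through the per-beat knots
   (isoelectric window center, z) is subtracted, per lead.  The
   fit-and-subtract step runs twice: one pass leaves the mid-knot
   interpolation residual of large slow wander (about 3–6 µV for 200 µV,
   0.3 Hz wander at 70 bpm knot spacing), and the second pass removes it.
   Fewer than three knots fall back to linear interpolation with a warning.
4. **Beat selection.** Beats labeled normal whose immediate neighbors are
   also normal are kept ("neighbors" read as one beat on each side; the
   source description is plural but unquantified).

## Numerical choices

* **Two Gram–Schmidt sweeps.** Modified Gram–Schmidt is used column by
  column for stability, and each column is orthogonalized twice ("twice is
  enough" reorthogonalization).  One sweep leaves the highest-degree
  columns of the ill-conditioned monomial matrix with O(1e−3) mutual
  overlap, which would break full-basis reconstruction; two sweeps give
  Gram errors at machine precision, far inside the reference bounds
  (3.4e−6 diagonal, 1.0e−5 off-diagonal for the first 10 functions).
* **Discrete vs continuous Legendre shapes.** The discrete construction
  orthogonalizes under the *sum* inner product on 32 points, not the
  integral.  Its degree-n columns therefore differ from unit-normalized
  samples of the continuous polynomials by an O(1/M²) quadrature term:
  1 − cosine similarity is 2.3e−3 (degree 2), 9.2e−3 (degree 3), 2.2e−2
  (degree 4) at M = 32, values pinned in the tests against an independent
  Householder-QR oracle and shrinking quadratically with M.  A stated
  acceptance threshold of 1 − 1e−6 for this similarity is not attainable by
  this construction; the corresponding acceptance test is intentionally
  left failing rather than weakened.
* **Sign conventions.** LPT columns are oriented so their value at x = +1
  is ≥ 0 (matching P_n(1) = 1); KLT eigenvectors are oriented so their
  inner product with the same-index LPT column is ≥ 0, exploiting the
  empirical similarity of the two bases; eigenvalue ties keep original
  order.  Signs are irrelevant to orthonormality but must be deterministic.
* **Covariance divisor.** Population form (1/K over K classes);
  eigenvectors are unaffected, and `robust_covariance(divisor = "K-1")` is
  available.  Coefficient standard deviations use the sample (n − 1)
  divisor; zero-variance coefficients are floored at 1e−12 with a warning
  so normalization stays defined.
* **Interpolation.** Amplitudes at fractional-sample offsets and the
  32-point window resampling use linear interpolation (at 250 Hz the native
  window holds 31 samples, so "32-sample resolution" requires a
  convention: an endpoint-inclusive uniform grid).
* **N_D = 5** for the Mahalanobis distance (configurable 1–9); five
  coefficients is what published trend plots display, and the source
  leaves N_D open.
* **Outlier rejection** before KLT training is a documented simplification
  of the original feature-space procedure: drop patterns whose RMS
  deviation from the per-class median pattern exceeds 4 times the median
  of those deviations.  Deterministic, and exact-median corpora degenerate
  gracefully (only exact matches kept).
* **Degenerate inputs.** Rank deficiency during orthonormalization,
  non-symmetric covariances, non-increasing beat times, empty intervals,
  empty windows and classes smaller than the fold count all raise typed
  errors or warnings rather than silently proceeding.

## The synthetic generator: what it emulates, and what not

`make_record()` emulates exactly the features the pipeline measures:

* an exactly flat PQ segment (true isoelectric 0) so isoelectric estimation
  has unambiguous ground truth;
* an analytically exact parametric ST window: level (µV) + slope (µV per
  100 ms, linear, centered at F + 100 ms) + scoop (peak µV at the window
  edges).  The scoop primitive is the *discrete-orthogonal* quadratic
  (3x² − 1 − c_M)/(2 − c_M) with c_M = 2/(M−1): the continuous quadratic
  P₂ has an 18 % projection onto the constant under the discrete inner
  product, which would mix level into every injected scoop; the
  discrete-orthogonal shape is precisely what LPT coefficient 3 measures.
  The injected ST deviation is held from the window end out to 230 ms and
  then tapered — ischaemic deviation persists into the ST-T region, and a
  hard return to baseline just past the measurement point would let the
  low-pass filter bleed baseline into a_80(60) (a ~10 % bias, visible when
  the hold is removed);
* triangular episode trajectories (linear from onset to extremum to
  offset) for ST parameters and heart rate; ischaemic episodes carry true
  ST deviation (> 50 µV by validation), heart-rate-related episodes carry
  *no* true deviation — their apparent ST change comes from moving the
  T wave toward the QRS (default shift −min(70, 1.8·Δhr) ms), which is what
  makes the classification task non-trivial;
* step axis shifts, sinusoidal baseline wander, white noise, and labeled
  wide ectopic beats at a configured rate;
* full determinism under the seed, with the caller's RNG state restored.

It does **not** emulate: realistic P/QRS/T microstructure (they are
Gaussian bumps and piecewise-linear ramps), respiratory or electrode-motion
artifact spectra, heart-rate variability beyond the episode trajectories,
or inter-patient morphology variation.  A green benchmark therefore
establishes that the pipeline and protocol are implemented correctly and
that the features separate the two episode mechanisms as constructed — not
that real-data classification accuracy is reproduced.  On real ambulatory
data the reference protocol reports CA ≈ 90 % (KLT) vs ≈ 82 % (LPT); the
synthetic benchmark is much easier (CA ≈ 99 % for both), so the acceptance
checks assert only the protocol-level properties (CA ≥ 85 %, KLT not more
than 5 points behind LPT).

Training-corpus defaults (class-conditional parameter distributions: no
deviation N(0, 15/15/6 µV) for level/slope/scoop; ischaemic level 60–250 µV
in magnitude, 75 % depressions, slope N(0, 60), scoop up to 50 µV;
heart-rate-related encroachment 30–70 ms; 10 µV sample noise) were chosen
once so that the per-coefficient standard deviations come out in the
descending order observed on real corpora, and are documented rather than
tuned.

## Evaluation protocol

Each annotated episode (one instance per episode and lead) is represented
by the mean normalized coefficient vector over a 20 s window centered on
the extremum, clipped to the episode bounds — only the extremum needs to be
located, not onset or offset.  Classifiers: kNN (Euclidean, vote ties to
the class with smaller mean neighbor distance), a Gini classification tree,
QDA (MASS), a least-squares SVM with (1 + x·x′)² kernel solved as a linear
system (the reference explicitly uses the least-squares formulation), and a
naive Bayes with per-feature Gaussian kernel densities.  Cross-validation
is stratified (the real data are imbalanced 1130 : 234, and unstratified
folds would be unstable), instances are canonically ordered before the
seeded shuffle so fold assignment is order-independent, confusion counts
are pooled over the folds of a repetition, and Se/Sp/CA are averaged over
repetitions.  Pool-then-average was chosen because per-fold metrics on
small folds are noisy; the source does not state its convention.

When an episode extremum must be *located* on a measured series (the
1-hour parameter-recovery check), the ST level series is smoothed with a
running median spanning roughly 20 s (matching the episode-feature window)
before taking the extremum: a triangle 20 minutes wide is locally flat at
its apex, and a 5-beat median cannot localize it under 10 µV measurement
noise.

## Known limitations

* WFDB support covers format-16 signal files with gain/baseline/units
  honored; beat annotations are read from an rdann-style text table, not
  the binary `.atr` format.
* The bundled amplitude-threshold beat detector is a convenience for
  annotation-free synthetic data only and is excluded from all acceptance
  surfaces.
* Normalization standard deviations should come from a trained corpus;
  when none is supplied they are estimated from the record itself with a
  provenance warning, which makes normalized coefficients record-relative.
* The apparent inconsistency between J-anchored wording (J + 80/60 ms,
  J + 20 ms) and F-anchored definitions (F + 160/120 ms, F + 60 ms) in the
  source is resolved in favor of the explicit F-offsets throughout.
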