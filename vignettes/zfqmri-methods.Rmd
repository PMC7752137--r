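---
title: "Quantitative MRI relaxometry and myelin morphometry: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI relaxometry and myelin morphometry: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zfqmri)
```

## What this package computes

`zfqmri` implements the quantitative-imaging side of phenotyping zebrafish
models of vanishing white matter disease: voxelwise T1/T2 relaxometry from
multi-TR / multi-TE spin-echo series, landmark-based rigid motion
correction, skull-normalized brain morphometry, white-matter ROI intensity
normalization, and perimeter-based G-ratio quantification from TEM fiber
contours.  Because no raw specimen images are available to ship, the
package carries a first-class synthetic-data module that generates digital
phantoms with known ground truth; every stage of the pipeline is validated
against that truth.

## Signal models and the gradient-descent fit

Magnitude signal in a saturation-recovery T1 series and a spin-echo T2
series follows the monoexponential models

$$S(TR) = M_0\,(1 - e^{-TR/T_1}), \qquad S(TE) = M_0\, e^{-TE/T_2},$$

with `TR`/`TE` in ms.  Both exponents are negative: the positive-exponent
variants are unbounded in `TR`/`TE` and non-physical for relaxation, so the
package implements the decaying forms throughout.

Fitting minimizes the **sum of squared residuals** over the time points
(not the mean; with a shared fixed learning rate the distinction only
rescales the step).  The default fitter is plain steepest descent with the
analytic gradients $\partial S/\partial M_0$ and $\partial S/\partial T$,
a single shared learning rate for both parameters, and fixed initial
constants:

| parameter | default | unit |
|---|---|---|
| `m0_init` | 8000 | signal units |
| `t1_init` / `t2_init` | 150 / 75 | ms |
| `loop_limit` | 75000 | iterations |
| `learning_rate` | 1e-6 | (signal units)$^{-2}$-ish, see below |
| `early_stop_tol` | 1e-10 | relative parameter change |
| `positivity_floor` | 1e-3 | ms |

The early stop is an addition for desk-scale runs: with `early_stop_tol =
0` the loop always runs to `loop_limit`, which reproduces the fixed-budget
behaviour exactly and is asserted in the tests.

### Conditioning, and why a scaled mode exists

The SSE Hessian of these two-parameter fits is severely ill-conditioned:
at the study's echo times its small eigenvalue is of order 1 while the
large one is of order $10^3$–$10^4$.  At learning rate $10^{-6}$ the slow
eigendirection — essentially the $M_0$ axis — moves by a factor of only
$\exp(-0.06)$ over the entire 75000-iteration budget.  Two practical
consequences, both verified numerically in the test suite:

* when the true $M_0$ is near the 8000 initialisation, the relaxation time
  converges through the fast direction and the round-trip error is far
  below 0.5%;
* when the true $M_0$ is far from 8000, the raw fit cannot reach the
  optimum in budget, and the relaxation time inherits a large compensating
  error.

The raw mode therefore carries its learning rate as a *dimensional*
constant tied to the expected signal scale; `fit_map()` warns when the
data's peak signal is more than a factor of 10 from `m0_init`.  For use at
arbitrary scales the package provides `mode = "scaled"`: per-parameter
steps scaled by the diagonal of the Gauss–Newton Hessian, backtracking on
the loss, and a 25% cap on the relative parameter change per iteration.
The scaled mode recovers $(M_0, T)$ over a grid of $M_0 \in [2000, 16000]$,
$T_1 \in [50, 600]$ ms, $T_2 \in [20, 200]$ ms to ~1e-10 within a few
thousand iterations, and is scale invariant (scaling the signals and
`m0_init` by $c$ scales $M_0$ by $c$ and leaves $T$ unchanged).  It is off
by default; the raw mode is the reference behaviour.

An independent check, `nls_oracle_fit()`, fits the same models by
log-linear regression (exact on clean T2 decays), the exact two-point
closed form $T_2 = (TE_2 - TE_1)/\ln(S_1/S_2)$, or Levenberg–Marquardt
nonlinear least squares from `minpack.lm`.  It is used only in tests and
QC, never as the fitter.

### Degenerate input and background

An all-zero signal vector returns a degenerate result (`m0 = 0`, `t = NA`,
`converged = FALSE`) rather than raising, and such voxels are dropped from
the fit mask.  The default mask keeps voxels whose peak signal across time
points exceeds 5% of the series maximum; an explicit mask overrides it.
Repeated acquisitions at a time point are arithmetically averaged (after
any alignment) before fitting.

## Motion correction

Sub-pixel inter-acquisition motion is modelled as an in-plane rigid
transform (rotation + translation, no scaling), estimated from named
landmarks — the two eye-lens centers and the vagal-lobe tip — by
closed-form 2D orthogonal Procrustes: centroid alignment, SVD of the 2×2
cross-covariance, reflections excluded.  The estimate is exact (residual
zero to machine precision) whenever the target is a true rigid image of
the source.  One transform per volume is estimated from one representative
slice's landmarks and applied to all slices, with bilinear interpolation
and zero fill outside the field of view (matching magnitude background).
Volumes are aligned to a designated reference time point; the per-volume
transforms are returned for QC.  Degenerate landmark configurations
(coincident points) make the rotation ill-posed; the estimator then
returns the translation-only transform and flags it.

Registration accuracy is quoted as the displacement error at the landmark
centroid, where the rotational component has no lever arm — this is the
error the aligned image actually sees near the anatomy of interest.

## Morphometry and group statistics

Brain size is measured as landmark-to-landmark Euclidean distances in mm
(per-axis voxel scaling): olfactory-bulb tip to tectum end (length),
maximum tectum width, maximum brain height, and skull width.  Each brain
measure is normalized to the same specimen's skull width, which removes
overall-size differences between genotypes.  Landmark placement is taken
as given (the original measurements were manual); automated detection is
out of scope.

Group comparisons use the two-tailed two-sample t-test, pooled-variance
Student's form by default with Welch's form by option.  No multiplicity
correction is applied by default, matching per-measure reporting.  The
t-test's p-value is validated against a numerically integrated t CDF and,
on a small discrete example, against an exhaustive permutation test —
where the t reference is documented to be only a coarse approximation.

## ROI intensity

White-matter signal is quantified as the mean of a 2×2-pixel ROI in the
periventricular grey zone divided by the mean of a 2×2-pixel ROI in the
optic tectum on the same slice, on a reference slice at the caudal end of
the rhombencephalic ventricle plus two more slices moving rostrally; the
per-fish summary is the arithmetic mean of the three per-slice ratios
(per-slice values are always emitted so alternates can be computed).  The
footprint convention is fixed bit-exactly: the block's lower-index corner
is `round(center - (size-1)/2)` in 0-based pixels.  The ratio direction
(white over grey) is recorded in outputs and flippable.  Ratios are
invariant to global intensity scaling by construction.

## G-ratio

From paired fiber contours the package computes the perimeter-based
G-ratio $g = P_{axon} / P_{myelin}$, with perimeter the closed polygonal
arc length.  Diameter and thickness use perimeter-equivalent-circle
conventions consistent with that definition ($d = P/\pi$, thickness
$= \Delta P / 2\pi$); area-equivalent variants are available by option,
and because the original definitions of diameter/thickness are not fully
specified, assertions about them are property-based (invariances, circle
limits) rather than value-based.  Contours are validated on ingest:
exactly one axon and one myelin boundary per fiber, at least three
vertices, simple polygons (brute-force segment-intersection check), axon
strictly inside myelin.  Binned G-ratio reporting by axon-diameter
quantile is available, anticipating that a caliber shift can masquerade as
a myelin-thickness change.

## The synthetic-data module

The phantom is an ellipsoidal brain inside an ellipsoidal skull shell on a
desk-scale grid (default 48×24×28 voxels at 0.1 mm; the study-scale
305×140×165 grid is constructible by configuration for profiling).  Design
choices, each made once:

* **Uniform in-brain M0 (8000).**  Tissue contrast is carried by T1/T2;
  proton-density differences between grey and white matter are small, and
  a uniform M0 matches the raw fitter's initialisation scale (see the
  conditioning discussion above — this is a study condition, not a
  convenience).
* **Signal-void skull (M0 = 0).**  Cortical bone is invisible on
  spin-echo magnitude images; the skull still defines the morphometric
  normalizer through its landmarks.
* **Compartments.**  Grey matter (T1 180 ms, T2 75 ms) and a
  periventricular white-matter band (T1 280 ms, T2 derived).  These are
  configuration values chosen so the study's TR/TE sets straddle the
  T1/T2 values, not claims about zebrafish tissue.  The white-matter T2
  default is derived from a target white/grey signal ratio at TE =
  36.6 ms: 0.743 for wild-type-like and 0.849 for mutant-like phantoms,
  i.e. T2 ≈ 46.6 and 56.2 ms against grey 75 ms.
* **Group geometry.**  Wild-type normalized length/width/height
  1.11/0.958/0.629; mutant 0.933/0.836/0.551 — the mutant brain is
  smaller and its white-matter signal closer to grey, the effect
  directions of interest.
* **Noise.**  Rician: $\sqrt{(S+n_1)^2 + n_2^2}$, $n_i \sim N(0,
  \sigma^2)$, as appropriate for magnitude reconstructions; the sample
  mean is validated against a numerically integrated Rician mean.
* **Motion.**  A per-acquisition rigid transform applied slice-wise;
  landmark tables move with the image, so registration can be tested
  against the exact inverse.
* **Cohorts.**  Per-specimen seeds fan out deterministically from one
  master seed (Lehmer step, 32-bit safe).  Between-specimen biological
  variability is a common size factor (CV 5% by default) on the brain
  with the skull fixed — so normalized measures carry the same CV — and a
  CV on white-matter T2.
* **Fibers.**  Concentric, optionally elliptical polygon pairs with the
  myelin contour the axon contour scaled by $1/g$; since the shapes are
  similar, the perimeter-based true g is exact by construction.  G-ratio
  draws use Normal(g\_mean, g\_sd) with out-of-range draws resampled and
  counted; defaults mirror the reported group statistics (0.593/0.085 and
  0.690/0.076).

What the phantom does **not** emulate: partial-volume voxels, B1/flip-angle
inhomogeneity, k-space/RARE reconstruction artifacts, susceptibility, or
anatomically realistic shapes.  Passing tests therefore demonstrate
correctness of the estimators under the stated models, not robustness to
every property of real scanner data.

## The smooth phantom and the motion benchmark

Comparing motion-corrected to motion-free fits on a piecewise-constant
phantom mostly measures bilinear interpolation error at tissue edges, not
registration quality.  The end-to-end benchmark therefore uses
`smooth_phantom()`: uniform M0, T1/T2 fields varying linearly by ±10%
across the grid, no background.  Bilinear resampling is exact on locally
linear fields, so the comparison isolates what it should.  The benchmark
fits both arms with the same settings (loop limit 20000 on a 32×16×12
grid) and compares median relative T1 error over an interior margin that
excludes the zero-filled border; the corrected arm is required to stay
within 2× the motion-free arm.

## Problem sizes and numerical choices

Default test problem sizes were chosen so each property is exercised at
meaningful scale: full-grid (48×24×28) noiseless and SNR-40 relaxometry
round-trips; 200 jitter trials for registration; 500-replicate power
simulations at n = 6 per group for morphometry (landmark-level, the
volumes are not needed) and ROI intensity (on a 24×12×14 cohort grid);
fiber cohorts of 200 per group.  Ties in ROI anchoring follow base R
`round` (half to even).  The positivity floor (1e-3 ms) only guards the
exponential against non-positive T during descent.  All randomness flows
from explicit seeds; identical configuration plus seed reproduces every
deterministic pipeline output bit-identically (checksummed in the tests).

## Known limitations

* The raw gradient-descent mode is scale-dependent by construction
  (dimensional learning rate) and is only accurate when true M0 is near
  its initialisation; this is faithful to the reference procedure and the
  scaled mode exists for everything else.
* Whether residuals were originally summed or averaged, and whether any
  step-size decay was used, is not stated anywhere authoritative; the
  choices here (sum, no decay) are recorded in every output sidecar so
  alternates can be compared.
* One transform per volume: within-volume (per-slice) motion is not
  modelled.
* The t-test is the only group statistic; multi-group ANOVA machinery is
  deliberately out of scope.
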