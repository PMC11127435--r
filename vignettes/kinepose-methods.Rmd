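---
title: "Movement monitoring pipelines with kinepose: models, parameters and design choices"
author: "kinepose authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement monitoring pipelines with kinepose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinepose)
```

## What the package models

`kinepose` implements the computational core of a camera-based
human-movement monitoring pipeline built on 2D keypoint skeletons. The
chain is:

1. **Field synthesis** — ground-truth joint *confidence maps* and limb
   *part affinity fields* rendered from known skeleton coordinates;
2. **Pose assembly** — recovery of per-person skeletons from those
   fields by peak detection, affinity line integrals and greedy limb
   matching;
3. **Shape standardization** — range normalization of keypoint
   sequences followed by per-frame Procrustes calibration;
4. **Kinematic features** — segment-wise polynomial fits of the
   calibrated trajectories with a goodness-of-fit score;
5. **Dimension reduction** — a five-stage PCA with strict train/test
   asymmetry;
6. **Classification** — a one-vs-rest support vector machine with a
   precision/sensitivity/specificity report suite.

Everything upstream of the classifier is deterministic given its
inputs; every stochastic stage (trajectory noise, data splits,
classifier fitting) is driven by a single run seed, so whole-pipeline
runs are bit-reproducible.

No trained detection network is involved: the confidence maps and
affinity fields that a network would predict are rendered directly from
ground-truth coordinates. This makes the association, calibration,
feature and classification stages testable in isolation and end to end,
at the price of not modelling detector failure modes (see
*Limitations*).

## The field model

For joint $j$ of person $n$ at true position $x_{j,n}$, the confidence
map value at grid point $q$ is the Gaussian
$s^*_{j,n}(q) = \exp(-\lVert q - x_{j,n}\rVert_2^2 / \sigma^2)$, and
the fused map takes the pointwise **maximum** over persons, preserving
every individual peak (a mean would flatten peaks where people
overlap). `sigma` defaults to 6 px on the default 128 × 128 grid
(3 px on the 64 × 64 benchmark grid), keeping neighbouring joints
resolvable while tolerating ±1 px quantization.

For limb $c$ with endpoints $x_{j_1,n}$, $x_{j_2,n}$, the affinity
field stores the unit vector $V = (x_{j_1,n} - x_{j_2,n}) /
\lVert x_{j_1,n} - x_{j_2,n}\rVert_2$ at every grid point lying on the
limb, defined as: projection onto the segment between the endpoints and
perpendicular distance at most `limbWidth` (default 4 px; 2 px on the
benchmark grid). Where several persons' bands overlap, vectors are
averaged over the nonzero contributions, so norms never exceed 1 and a
single person's support carries exactly unit vectors.

The candidate-pair reliability is the discretized line integral
$E = \tfrac1K \sum_k L_c(q(u_k)) \cdot \widehat{d}$ with
$q(u) = (1-u)\,d_{j_1} + u\,d_{j_2}$ and $K = 10$ uniform samples.
Using the **mean** rather than the raw sum makes $E$ scale-free: a
perfectly aligned field scores exactly 1 whatever $K$, so the
acceptance threshold `eMin = 0.5` has a fixed meaning. One subtlety is
deliberate: the rendered field of limb $(j_1, j_2)$ points from $j_2$
towards $j_1$, while the integral projects along the direction from its
first to its second argument; `matchLimbs()` therefore scores pairs
from the $j_2$-candidate towards the $j_1$-candidate so that correct
connections score $+1$, not $-1$.

Matching is greedy: per limb type, all cross pairs are sorted by
descending $E$ (ties broken by candidate indices) and accepted while
both endpoints are unused and $E \ge$ `eMin`; limbs sharing a candidate
merge into skeletons. Because the limb graph is a tree, a merged
skeleton can never hold two candidates of the same joint type. On
scenes of separated persons the greedy total equals the exhaustive
optimal assignment — the test suite verifies this against a
brute-force oracle on 200 scenes.

Masked field losses are also provided: $f_R$ sums
$w(q)\lVert\text{pred}-\text{true}\rVert_2^2$ over joint maps, $f_M$
the analogous vector norm over limb fields, and the total loss sums
$f_R + f_M$ over refinement stages. The 0/1 weight $w(q)$ zeroes
unannotated points so missing labels are never penalized.

## The joint model

The skeleton has 15 indexed positions (0–14) but 14 *measured* points:
position 0, the hip centre, is derived per frame as the midpoint of the
two femur heads. The segment partition used for features is BB (hip
centre, spine, neck), UB (left wrist/elbow/shoulder, neck, right
shoulder/elbow/wrist) and LB (left ankle/knee/hip, hip centre, right
hip/knee/ankle); the hip centre and neck are shared between segments,
and segment sizes are fixed at 3/7/7.

## Shape standardization

Raw keypoint sequences are first range-normalized: per person and
**per sequence** (not per frame, which would erase temporal amplitude),
x is mapped affinely onto $[-200, 200]$ and y onto $[-800, 800]$ —
an aspect ratio matching the roughly 1:4 shoulder-width-to-height
proportion of a standing body. The defining extrema map exactly to the
bounds.

Procrustes calibration then aligns every frame to a model pose in the
fixed order **translate → scale → rotate**: centroid removal, division
of each axis by its RMS norm $S_F = \sqrt{\tfrac1N\sum \hat{x}_i^2}$,
and the closed-form least-squares rotation
$\theta = \operatorname{atan2}\!\big(\sum(x_s y_m - y_s x_m),\,
\sum(x_s x_m + y_s y_m)\big)$. Rotation is restricted to pure rotation
(no reflection), since a reflection would swap left and right anatomy.
The default model pose is the mean normalized frame of the *training*
set.

The per-axis scaling is deliberately anisotropic. This has a
consequence worth stating: anisotropic scaling does not commute with
rotation, so an arbitrary rotation composed with anisotropic stretch is
not exactly invertible by this chain. Exact recovery (and exact
invariance of the calibrated output) holds when the model pose's
centred x and y coordinates are uncorrelated — true for any
left-right-symmetric pose, including the shipped base pose — and the
stretch acts on the RMS-normalized axes. The recovery tests are
constructed in that regime; for strongly asymmetric model poses a small
residual $P_d^2$ remains and is reported in the per-frame transform
records rather than hidden.

## Kinematic features

Each calibrated sequence is summarized per segment (BB, UB, LB) and
axis (x, y) by fitting the segment centroid's trajectory against
normalized time $u \in [0,1]$ with a least-squares polynomial
$p(u) = c_0 + c_1 u + \dots + c_n u^n$, scored by
$R^2 = 1 - \sum(y-\hat y)^2 / \sum(y-\bar y)^2$. Normalizing the time
axis keeps the Vandermonde system well conditioned and makes features
invariant to uniform temporal shift. A constant target with zero
residuals returns $R^2 = 1$ by limit convention; with nonzero residuals
it is an error rather than a silent `NaN`.

The polynomial degree defaults to 5: low enough to stay stable on
40-frame windows, high enough to capture one-to-two movement cycles'
shape. The feature vector concatenates, in fixed order BB.x, BB.y,
UB.x, UB.y, LB.x, LB.y, each block's coefficients and $R^2$, giving
$6(n+2)$ values (42 at the default degree). Fitting centroid
trajectories over time (rather than spatial y-vs-x curves within a
frame) was chosen because temporal shape is what separates activities;
a per-frame spatial fit was considered and rejected — the smallest
segment holds only three points, which cannot support the default
degree and would break the fixed-length feature contract.

## Dimension reduction

PCA proceeds in five stages: training mean, unnormalized scatter matrix
$A = \sum_i (X_i - \bar X)^\top (X_i - \bar X)$, eigendecomposition,
selection of the smallest leading component set whose cumulative
variance ratio reaches `precision` (default 0.95), and projection of
centred data. The constant $1/(n-1)$ is omitted from the scatter on
purpose — it changes neither eigenvectors nor variance ratios.
Eigenvector signs are fixed (largest-magnitude entry positive) so
models are deterministic. Two projection modes exist: `"standard"`
projects on the retained eigenvectors; `"eigenscaled"` additionally scales
each component by its eigenvalue — a per-component positive rescaling
retained for audit that changes no selection decision and, after
feature standardization, no downstream separability.

Test batches are always centred with the **training** mean. This
asymmetry matters: centring validation data with its own batch mean is
a form of information leakage, and the label-permutation control in the
benchmark exists precisely to catch such leaks — with permuted labels
the whole pipeline must collapse to chance accuracy.

## Classification and metrics

The primary classifier is a soft-margin SVM with RBF kernel
(`C = 1`, `gamma = 1/(d · mean feature variance)`), trained one-vs-rest
(one binary machine per class, prediction by the largest decision
value) on standardized features. The data are split 70/30 by seeded
stratified random sampling. A secondary baseline — a single
hidden-layer network with ReLU activation, softmax output and plain SGD
at learning rate 0.001 — is provided via `trainMLP()` for comparison;
the SVM is the headline model.

Reports read the confusion matrix one-vs-rest per class:
precision $TP/(TP+FP)$, sensitivity $TP/(TP+FN)$, specificity
$TN/(TN+FP)$, in percent, macro-averaged over classes (a metric with a
zero denominator is `NA` and excluded from the average — the choice of
averaging is stated here because conventions differ).

## The synthetic generator and what it does (not) show

Each activity class is a set of sinusoidal components around a neutral
standing pose: per-joint amplitudes (fractions of body height), a
fundamental frequency, and phases (legs and arms anti-phase for
running, bilaterally synchronous for the aerobics archetype, right-arm
dominant for table tennis). Gaussian coordinate noise (default sd 1 px)
stands in for detector jitter. The archetypes live in an editable YAML
table (`inst/extdata/activity_classes.yaml`), not in code.

The benchmark conditions are: three classes, 60 sequences per class,
40 frames at 20 fps, rendered and re-detected on a 64 × 64 grid with
`sigma` 3 px and limb half-width 2 px, degree-5 fits, PCA precision
0.95, RBF SVM, 70/30 split. These sizes were chosen as the package's
documented study conditions; the per-sequence cost is dominated by
rendering and re-detecting 40 scenes.

What passing tests show: the association, calibration, feature,
reduction and classification machinery is internally correct, exactly
reproduces its closed-form identities, and separates periodic motion
classes that differ in amplitude structure and tempo. What they do
**not** show: robustness to real video — occlusion, detector false
positives, non-periodic motion, person tracking across frames, camera
distortion — none of which the generator emulates.

## Numerical choices and degenerate inputs

* Peak detection: local maxima ≥ `threshold` (default 0.1),
  non-maximum suppression within `nmsRadius` (default `sigma`);
  candidates sorted by descending score with (row, column) tie-breaks,
  so results are deterministic.
* Affinity sampling uses nearest-grid-point lookup; candidate pairs at
  identical positions are an error (zero-length direction).
* Coincident limb endpoints skip the limb with a warning rather than
  dividing by zero.
* Zero variance on an axis (scaling), degenerate ranges
  (normalization), underdetermined fits, single-class training sets
  and unknown class tokens are all hard errors that name the offending
  axis/joint/flag.
* Occasional missing joints during sequence re-detection are filled by
  carrying the previous frame (leading gaps back-filled); a joint never
  recovered at all is an error.

## Limitations

* Frame-by-frame assembly only; no temporal identity tracking.
* The anisotropic-scaling/rotation interaction described above.
* Polynomial features assume roughly periodic, stationary motion
  within the window; spline or spectral features are out of scope.
* Reported benchmark numbers are properties of the synthetic
  conditions, not claims about human-subject recordings.
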