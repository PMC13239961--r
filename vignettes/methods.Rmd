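---
title: "Methods: rotational dose perturbation QA with SSIM and dosiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rotational dose perturbation QA with SSIM and dosiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rotqa)
```

# The problem

Stereotactic body radiotherapy (SBRT) delivers ablative doses with steep
spatial gradients, so small rotational setup errors (1-5 degrees about
the isocenter) can measurably distort the delivered dose distribution.
Conventional planar QA metrics — gamma passing rates and dose-difference
(DD) passing rates — score pointwise agreement and are known to respond
weakly to spatially coherent distortions. The structural similarity
index (SSIM), which compares local luminance, contrast and structure,
is a candidate metric with higher sensitivity to exactly this failure
mode.

`rotqa` implements the full analysis chain needed to study this
question on synthetic data: a generator of SBRT-like dose volumes and
rotated planar detector measurements, the standardized preprocessing
and scoring metrics (SSIM, gamma, DD, delta-V100), IBSI-style radiomic
and dosiomic feature extraction, and an attribution-based predictive
model of SSIM degradation.

# Dose comparison metrics

## SSIM

For two planes $x, y$, local windows give means $\mu_x, \mu_y$,
population variances $\sigma_x^2, \sigma_y^2$ and covariance
$\sigma_{xy}$. With $C_1 = (K_1 L)^2$, $C_2 = (K_2 L)^2$,
$C_3 = C_2/2$, the component comparisons are

$$l = \frac{2\mu_x\mu_y + C_1}{\mu_x^2 + \mu_y^2 + C_1},\qquad
  c = \frac{2\sigma_x\sigma_y + C_2}{\sigma_x^2 + \sigma_y^2 + C_2},\qquad
  s = \frac{\sigma_{xy} + C_3}{\sigma_x\sigma_y + C_3},$$

and with unit exponents their product collapses to the familiar
combined form

$$\mathrm{SSIM} = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
                      {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}.$$

Defaults follow the common image-library convention: $K_1 = 0.01$,
$K_2 = 0.03$, a $7\times 7$ uniform sliding window restricted to fully
interior positions, the scalar SSIM as the mean of the local map, and
$L$ equal to the maximum of the two planes being compared (a global
single-window mode is available via `window = 0`). Some printed
statements of the contrast comparison carry $C_1$ in its numerator;
`rotqa` uses $C_2$ throughout, which is the only choice consistent with
the combined closed form, and the test suite pins the identity
$l \cdot c \cdot s = \mathrm{SSIM}$ to $10^{-12}$.

## Gamma and dose difference

`gamma_map()` computes, per scored reference point, the minimum over
nearby evaluated positions of
$\sqrt{d^2/\mathrm{DTA}^2 + \Delta D^2/\mathrm{DD}^2}$. The evaluation
plane is bilinearly upsampled (factor 10 by default) and searched
within 3 DTA of each reference point; dose differences are normalized
either to the reference plane maximum ("global", the default) or to the
local reference dose. Scored points are exactly the entries surviving
the 70% low-dose preprocessing threshold in the reference; relative-
dose (RD) mode self-normalizes each plane before comparison while
absolute-dose (AD) mode compares in Gy. `dose_difference_pass_rate()`
is the same criterion with the spatial search removed. Both the
brute-force equivalence of the gamma search and the monotonicity of
passing rates in the criterion (1%/1mm $\le$ 1.5%/1.5mm $\le$ 2%/2mm)
are enforced by tests.

## Delta-V100

`delta_v100()` is the drop in target V100 (percent of target voxels at
or above the prescription dose) between the unrotated and rotated
volumes; positive values mean coverage loss. The sign convention makes
a negative SSIM-vs-delta-V100 correlation the expected direction.

# Plane preprocessing

Measured or simulated planes pass through a fixed pipeline before any
metric: bilinear resampling to $45\times45$ over the plane's physical
extent, zeroing of entries strictly below 70% of the plane maximum
(ties kept — the literal reading of "below the threshold"), then
normalization. The threshold uses each plane's own maximum by default
(a pair-shared reference maximum is available), and thresholding after
interpolation follows the order in which the measurement protocol
describes the steps; both choices are configurable. The pipeline is
idempotent at its own settings.

# The synthetic cohort generator

The generator replaces phantom measurements that are not publicly
available. It emulates the acquisition geometry rather than any
specific plan: a planar diode array with a 77.00 mm x 77.00 mm
effective area sampled as a regular 45 x 45 grid (1.75 mm pitch), a
two-stage protocol (stage 1: 5 magnitudes x 3 single directions per
plan on the 1.5-4.5 degree grid; stage 2: one record per plan with 2
or 3 axes perturbed at continuous angles from the same range), and
additive Gaussian measurement noise with SD equal to 1% of the plane
maximum (diode-array repeatability is at the percent level).

A synthetic plan is a superposition of three mildly anisotropic
Gaussian lobes placed on a ring around the isocenter projection
(radius 19-21 mm, azimuths evenly spread with jitter), each offset
3.7-5.5 mm from the measurement plane, with near-equal amplitudes
(0.9-1), per-lobe sizes of roughly 4-9 mm scaled by a plan-level
factor (0.8-1.3), and a multiplicative "crossfire ripple"
(amplitude 0.02-0.35, wavelength 12-18 mm, obliquely oriented
wavevector) standing in for the in-target dose heterogeneity that
cross-firing beams produce. The peak dose is drawn from 40-70 Gy and
the prescription is the 70% isodose, the common prescription line for
CyberKnife-style plans; the target mask is exactly the prescription
isodose set.

Three geometric choices matter most, and each was fixed after explicit
design experiments:

* **The plan isocenter sits 15 mm off the measurement plane.** The
  rotation axis passes through the isocenter; when the axis lies in
  the detector plane, pitch and roll only shift which slice is
  sampled, and a smooth dose field changes mostly by a multiplicative
  factor that relative normalization removes — making out-of-plane
  rotations nearly invisible to SSIM, contrary to the measured
  behavior this generator must emulate (out-of-plane correlations as
  strong as in-plane ones). An off-plane isocenter gives pitch and
  roll a uniform in-plane translation lever (offset x angle), the same
  mechanism that makes yaw effective, and is a realistic property of
  phantom QA geometry, where the plan isocenter need not lie in the
  detector plane.
* **Lobes are moderately off-plane with near-equal amplitudes.** The
  70% threshold silently erases any lobe whose planar amplitude falls
  below 70% of the plane maximum; deep or weak satellites contribute
  nothing to the scored region. Moderate offsets (|z| up to ~5.5 mm at
  lobe sizes of 4-12 mm) keep several lobes in the scored footprint
  while still giving each plan through-plane structure.
* **Azimuthally spread ring placement.** A single off-axis lobe
  cluster has a lever arm about one in-plane axis but not the other,
  which makes per-plan sensitivity to pitch vs roll close to a coin
  flip and dilutes pooled correlations; even azimuthal spread gives
  every plan comparable lever arms about both axes.

Rotations are applied to the dose volume with a fixed detector plane
(equivalent to rotating the phantom), by inverse-mapping trilinear
resampling about the isocenter, with out-of-field voxels set to zero.
The axis convention is a patient-like right-handed frame: UP = pitch
about the left-right axis, RO = roll about the anterior-posterior
axis, CW = yaw about the superior-inferior axis, clockwise when viewed
from above; the mapping is documented in `rotation_matrix()` and
configurable through the rotation arguments.

What the generator does **not** emulate: detector diode layout (the
1,013-diode geometry is not public; the standardized interpolation to
45 x 45 makes downstream stages insensitive to this), beam models,
couch kinematics, anatomy-driven heterogeneity, delivery-time effects,
and any specific clinical plan. Passing tests on this cohort therefore
demonstrate correctness of the metrics, features and modeling chain
and qualitative reproduction of the rotational-degradation phenomenon,
not quantitative agreement with any physical measurement.

# Feature extraction

Radiomics (per plan, target mask, original volume only): the 18
standard first-order descriptors and 14 mesh/moment-based 3D shape
descriptors — 32 features. Dosiomics (per plan, whole dose field): 18
first-order + 75 texture features (GLCM 24, GLRLM 16, GLSZM 16, GLDM
14, NGTDM 5) on the original volume, plus the same 93 first-order +
texture features on each of the 8 subbands of a single-level 3D
wavelet decomposition — 744 wavelet features, 837 in total. Shape
features are not re-extracted for dose (they would duplicate the
imaging ones). Feature definitions follow the IBSI-aligned standard
set with the common defaults: symmetric GLCM, distance-1
26-neighbourhood, 13 unique directions with feature-level averaging,
fixed-bin-width discretization anchored at the masked minimum (25
intensity units for images, 1 Gy for dose), and volumes resampled to
1 mm isotropic spacing when a resampling target is configured. The
wavelet is the orthonormal coiflet-1, implemented as an exact
orthogonal periodized transform so that subband energies partition the
input energy (a property the tests check to 1e-8); subbands are
reconstructed to the input shape, i.e. each band is an orthogonal
projection of the input.

Two numerical details: shape meshes are built by marching tetrahedra
on a lightly Gaussian-smoothed indicator (sigma = 1 voxel, iso-level
0.5), which removes the voxelization staircase that otherwise inflates
surface area by tens of percent; masks only a voxel or two across fall
back to meshing the raw indicator. Maximum-diameter features use
boundary-voxel distances with deterministic thinning above 8000
boundary points.

# Modeling

Records are split 70/30 at the plan level (`grouped_split()`), so no
plan geometry appears on both sides. Feature selection is two-stage,
on training rows only: each feature group (radiomics, dosiomics) is
ranked independently by mean absolute tree-path attribution (SHAP-style
contributions from a gradient-boosted ensemble, averaged over three
independently seeded ensembles for stability at small plan counts) and
the top 17 per group are kept; a fresh model re-ranks the merged set
and features holding at least 1% of the total attribution mass are
retained. The 1% floor makes "significant global contribution"
concrete; both the floor and k are configurable, with k = 17 adopted
from the observed per-group retention of the study this package
models.

The model search replaces genetic-programming AutoML with a fixed,
seeded candidate family — OLS, ridge and lasso at fixed regularization
strengths, gradient-boosted trees at two depths, and a random forest —
scored by grouped 10-fold cross-validated R-squared on the training
plans. Two details are deliberate: linear candidates carry *fixed*
penalty strengths so that all tuning happens in the grouped outer CV
(records of one plan are near-duplicates, so any record-level internal
CV such as `cv.glmnet`'s would leak across the grouping and
systematically pick near-zero regularization), and candidate scoring
pools held-fold predictions into a single R-squared. The winner is
refit on all training rows and reported on the held-out plans as
R-squared, MAE, RMSE and MedAE. Three scenarios run on one identical
split: full (selected features + the three angle magnitudes),
rotation-only (3 inputs), features-only.

Features are min-max scaled to the training range; test rows may fall
outside [0, 1], and constant training columns map to 0.

# Statistics

`pearson_cor()` reports the product-moment correlation with the
two-sided p-value from the t-transform on n-2 degrees of freedom; no
multiple-testing correction is applied (matching the practice of the
study being modeled — raw p-values are reported). `direction_analysis()`
stratifies records into UP/RO/CW (single-direction), MULTI (2-3 axes)
and POOLED (both phases) groups; each metric is correlated against the
total absolute angle, the MULTI and POOLED groups additionally against
the direction count, and each group reports the proportion of records
whose 2%/2mm gamma passing rate exceeds the 95% clinical threshold.
The POOLED group exists because a direction-count correlation computed
on the multi-axis subset alone has a sample size of one record per
plan; pooling both acquisition phases, with direction count (1-3) as
the independent variable, is the design with meaningful power and the
one the two-phase protocol describes.

# Known limitations and tensions

* The synthetic emulation has one variance budget and two claims on
  it. Strong pooled SSIM-angle correlations per direction require the
  angle response to dominate plan-to-plan variation, while a
  features-only model that beats a rotation-only model requires
  plan-to-plan variation (visible to texture features) to dominate the
  angle response. These pull in opposite directions; this generator
  prioritizes the per-direction correlation structure. In practice the
  full model outranks the rotation-only model, but the features-only
  scenario — whose information is limited to plan-level texture, with
  no access to angles — typically lands below the rotation-only one on
  this cohort, unlike on the real measurements this package models.
  Much of the plan-to-plan response variation here is geometric
  (lobe placement relative to the rotation axes) and is invisible to
  orientation-averaged, translation-invariant features by
  construction.
* SSIM's structure term is scale-invariant, so texture *amplitude*
  does not modulate rotational sensitivity; texture spatial scale and
  footprint size do. Feature sets built only from amplitude-sensitive
  descriptors would not predict SSIM degradation.
* Trilinear resampling bounds the fidelity of rotations to
  $O(h^2/\sigma^2)$; with 2.75 mm voxels and 4-12 mm features the
  relative error is at the percent level, which the rotation tests
  account for explicitly.
* Default problem sizes — 40 plans, 32-cubed volumes at 2.75 mm for the
  cohort, 64-cubed at 1 mm for the feature-census check — were chosen
  so a complete cohort analysis runs in minutes on one core while
  keeping lobe sizes several voxels wide; all are configurable.

# Reproducibility

Every stochastic step derives its stream from one master seed through
`derive_seed()` (a deterministic 31-bit hash), and `with_seed()`
restores the caller's RNG state, so cohorts, selections and model
searches are pure functions of their configuration. `run_all()` writes
every stage's table as plain CSV plus a JSON manifest carrying the
seeds; re-running an identical configuration reproduces the CSVs
bit-identically, and deleting a stage's outputs resumes the pipeline
from that stage.
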