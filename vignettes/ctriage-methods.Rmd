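---
title: "Normative-atlas anomaly triage for head CT: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative-atlas anomaly triage for head CT: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctriage)
```

## The problem

Most supervised detectors for head CT answer one question ("is there a
bleed?"). A normative-modelling detector instead asks: *does this scan
look like a normal scan?* It learns the distribution of normal appearance
voxel by voxel, flags everything that deviates, and triages the patient
before a radiologist ever opens the study. The appeal is weak
supervision: training needs only scans globally labelled "normal", not
voxel-wise annotations, and the detector is not limited to pathology
classes it has seen.

`ctriage` implements that pipeline end to end — spatial normalization,
voxel-wise Gaussian atlas, outlier scoring, two-threshold triage — plus
the evaluation statistics of a two-run reader study and a synthetic
phantom generator that makes all of it testable at desk scale without
clinical data.

## The normative model

All training scans are registered to a common template. At every brain
voxel $v$ the registered training intensities are modelled as Gaussian;
`fit_atlas()` estimates the sample mean $\mu_v$ and sample SD $\sigma_v$
(denominator $n-1$) and derives acceptance bounds

$$L_v = \mu_v - k\,\sigma_v, \qquad U_v = \mu_v + k\,\sigma_v.$$

A scored voxel is an **outlier** iff it lies in the brain mask and its
intensity falls strictly outside $[L_v, U_v]$. The patient-level
**anomaly score** is the ratio of outlier voxels to all brain-mask
voxels, $s \in [0, 1]$, computed exactly as a voxel-count quotient.

Parameter choices, all exposed in `ctriage_config()`:

* **`k = 2.576`** (SD units). The bound half-width is stated in the
  underlying method only as a confidence interval on the fitted
  densities; we fix the default at the 99% two-sided Gaussian quantile,
  so a perfectly normal scan is expected to flag $2\Phi(-k) \approx 1\%$
  of brain voxels. Any other coverage can be configured.
* **`sigma_min = 1` HU.** A floor on $\sigma_v$ prevents zero-width
  bounds at degenerate voxels (e.g. constant training intensities).
* **Intensity clipping to $[-100, 200]$ HU** before fitting and before
  scoring — a brain display window. Whether the original tool fitted raw
  or windowed HU is not documented; the window is therefore a
  configuration choice, not a claim of fidelity, and scan and atlas are
  always clipped identically so the comparison is consistent.
* Voxels outside the brain mask carry `NA` statistics and are never
  scored.

With a finite training set the empirical bounds are slightly wider than
the population ones, so held-out coverage is a bit above $2\Phi(-k)$
(about 1.1% at $n_{\text{train}} = 200$, $k = 2.576$); the tests assert
the 1% ± 0.3% band at exactly that training size.

Brain masks come from `extract_brain_mask()`: HU windowing to
$[0, 100]$, morphological opening and closing with ball structuring
elements, then the largest 6-connected component. Air and the dense
skull shell fall outside the window by construction.

## Triage

`calibrate_thresholds()` turns labelled validation scores into a
threshold pair under the asymmetric-cost objective *minimize the false
positive rate subject to a false omission rate of zero*: a missed
pathological scan is unacceptable, an unnecessary review is merely
costly. The estimator places

$$T_\text{upper} = \max\{s_i : \text{normal}\}, \qquad
  T_\text{lower} = \min\bigl(\min\{s_i : \text{pathological}\},\,
  T_\text{upper}\bigr),$$

and `triage()` labels with strict inequalities: $s < T_\text{lower}$ is
*normal*, $s > T_\text{upper}$ is *pathological*, anything else —
including scores exactly on a threshold — is *inconclusive*. On the
calibration set this guarantees FOR = 0 and FPR = 0 by construction, and
among all threshold pairs satisfying those constraints it is the
tightest, i.e. it maximizes the conclusive yield. When the classes
separate, the band collapses ($T_\text{lower} = T_\text{upper}$) rather
than inverting. The underlying method states the objective but not the
estimator; this reconstruction is the package's design choice.
Thresholds are calibrated and stored per scanner/atlas tag.

Two optional margins widen the band outward without touching the
calibration-set guarantees: `margin` is subtracted from
$T_\text{lower}$, and `margin_upper` is added to $T_\text{upper}$. The
upper margin matters for generalization: an extreme-value threshold
placed exactly at the maximum of $n$ calibration normals is exceeded by
a fresh normal scan with probability $1/(n+1)$ — by exchangeability,
regardless of how well the classes separate — so with margin 0 the
zero-false-positive property cannot survive contact with new data at
realistic calibration sizes. The package's held-out synthetic studies
therefore use calibration cohorts sized like a realistic validation set
(20 normal and 10 pathological scans per replicate, against 6 + 6
held-out scans) and calibrate with `margin_upper` set to three SDs of
the normal calibration scores, which places $T_\text{upper}$ above the
normal score distribution while staying far below the pathological
scores;
under that condition, held-out false-omission and false-positive rates
are zero in ≥95% of seeded replicates and every inconclusive label
falls on a normal scan. Both margins default to 0, which reproduces
the bare extreme-score rule.

## Registration

The original system used a multi-stage external registration framework;
its internals are not part of this package's scope. `register()`
provides a deliberately simple, pluggable replacement: `identity`,
`translation` (3 parameters) and `affine` (translation + Euler rotations
+ anisotropic log-scales, 9 parameters), optimized over a mean-squared
error or negative normalized cross-correlation objective with a 2-level
multiresolution pyramid, a translation-first initialization and BFGS
with numeric gradients. Transforms use the pull convention (template
coordinates → moving coordinates) and serialize as plain-text 4×4
matrices; an `engine` argument accepts any external registration
function in their place.

Two numerical details matter more than the optimizer:

* **Interpolation-blur bias.** The moving image is interpolated at every
  candidate pose while the template is not. Trilinear interpolation
  blurs by an amount that depends on the sub-voxel offset (variance
  $w(1-w) \le 1/4$ voxel² per axis), so a plain MSE objective prefers
  poses that *match blur*, not poses that match geometry — on smooth
  phantoms the optimum can sit 1–3° away from the true rotation. The
  metric therefore samples the moving image with a quadratic B-spline
  kernel, whose blur is constant (exactly 1/4 voxel² per axis,
  independent of offset), and convolves the template with the matching
  discrete [1/8, 3/4, 1/8] kernel. Both sides then carry identical blur
  at every pose and the bias term vanishes; recovery errors on smooth
  phantoms drop to ≲0.3° and ≲0.1 voxel. Both images are additionally
  Gaussian-smoothed (`smooth_sigma = 1` voxel) to widen the capture
  basin. The *output* image is still produced with true trilinear
  interpolation (nearest-neighbour for masks).
* **Monotonicity guard.** The returned transform never scores worse than
  the initialization on the reported objective; if optimization fails to
  improve, the identity is returned.

Registration accuracy is validated by known-transform recovery: phantoms
are sampled analytically at a transformed pose (no interpolation in the
ground truth), using smooth-edged scenes (`edge_width = 1.2` voxels)
with visible internal anatomy, and the recovered transform must invert
the true pose within 0.5 voxel and 1°.

## The phantom generator

`phantom_spec()` describes an ellipsoidal brain (default semi-axes
11×13×9 voxels on a 32³, 1 mm grid) of 35 HU tissue inside a 700 HU
skull shell on a −1000 HU air background. Normal scans add two Gaussian
variation components: a smooth spatial texture field (SD 3 HU,
correlation length ≈ 2 voxels, generated by FFT smoothing of white
noise) and independent per-voxel noise (SD 5 HU) — so per-voxel
intensities are Gaussian around the template with SD
$\sqrt{3^2 + 5^2} \approx 5.8$ HU, the property the atlas model assumes.
A fixed set of smooth intensity blobs ("anatomy", drawn once per phantom
seed) gives the template stable internal structure, as real brains have;
misalignment is opt-in via small random rigid jitters.

Pathological scans (`simulate_pathological_scan()`) add a signed HU
contrast inside ellipsoidal lesions with random axis ratios — positive
for hyperdense, bleed-like findings, negative for hypodense, stroke-like
ones. Lesion placement rejection-samples centers inside the eroded brain
mask and voxelizes by trimming to the exact target count, so the
realized lesion fraction equals the requested fraction up to a single
voxel and lesions always lie strictly inside the brain. Scoring such a
phantom at contrast $\ge 8\sigma$ should yield
$s \approx f + 2\Phi(-k)(1 - f)$, which the tests assert within 0.01.

What the generator deliberately does **not** emulate: beam hardening,
partial-volume averaging (edges are crisp by default; the smooth-edge
mode exists for registration studies), anatomical variability between
subjects beyond the random texture, and any pathology appearance beyond
an additive contrast. Passing tests on these phantoms validate the
statistical machinery — calibration of the bounds, exactness of the
score, threshold guarantees — not clinical performance on real CTs.

## The reader-study simulator

`simulate_reader_study()` emulates a two-run crossover (with and without
triage support) of four readers — two experienced, two inexperienced —
over a cohort of 40 normal and 40 pathological scans whose finding
classes follow the documented frequency mix (tumors and subacute strokes
most common, 89 finding classes in total, mean 2.2 per pathological
scan). Its default parameters are the study conditions:

* per-(run, experience) misclassification probabilities — e.g. 4/80
  false positives for experienced readers without support, 0 with
  support;
* truncated-normal reporting times (floor 5 s) per (run, experience,
  ground truth) with the documented group means/SDs (e.g. 59.6 ± 7.8 s
  without vs 46.3 ± 5.0 s with support on normal scans);
* per-run probabilities of missing an individual finding class (30/356
  without, 17/356 with support);
* 5-point Likert confidence per (run, experience). Because rounding and
  clamping a Gaussian to 1–5 shifts its moments (naively simulating
  N(4.30, 0.84) yields a mean near 4.21), the simulator moment-matches a
  latent Gaussian by least squares on the closed-form discretized
  moments (`likert_latent_params()`), so the discrete scores reproduce
  the target mean ± SD.

`confusion_metrics()` (pathological = positive class) reports
sensitivity, specificity, PPV and NPV with explicit `NA` markers for
undefined denominators. Display rounding is half-up to one decimal,
matching how such percentages are conventionally printed; note R's own
`round()` rounds half to even. `completeness()` counts (reader, scan,
finding-class) opportunities on pathological scans. Reporting-time
reductions are $\Delta RT = 100 (\bar t_{\text{no ai}} - \bar
t_{\text{ai}})/\bar t_{\text{no ai}}$.

Two statistical tests are provided. `paired_t_test()` wraps the standard
paired Student's t test with explicit degenerate results for zero
variance. `wilcoxon_signed_rank()` is implemented in-package because the
commonly available implementations cannot compute exact p-values under
ties: it excludes zero differences, assigns midranks, and for $n \le 25$
computes the exact null distribution of the positive-rank sum by dynamic
programming over doubled midranks (valid with ties); above that it uses
the normal approximation with tie correction and continuity correction.
The exact path is verified against full $2^n$ enumeration in the tests.
P-values on simulated records are reported but are not anchors for
anything: the per-scan data behind the published p-values are not
available.

## Problem sizes and numerical conventions

* Test and acceptance studies run at 32³ (atlas pipeline: 200 training
  scans, 50 held-out normals, 21 lesion phantoms) and 24³ (calibration
  replicates); registration recovery uses 20 seeded trials. These sizes
  put every Monte-Carlo band in the tests at 4 standard errors or more.
* Boundary conventions are fixed once: a voxel exactly on a normative
  bound is *not* an outlier; a score exactly on a triage threshold is
  *inconclusive*. Both are measure-zero choices made for determinism.
* Every generator is bitwise-reproducible under its seed; the RNG state
  of the caller is saved and restored around all internal seeding.
* Outlier masks receive no post-processing (no minimum cluster size):
  whether the original tool filtered them is undocumented, and adding an
  undocumented filter would change the score definition.

## Known limitations

* The Gaussian model is per-voxel: no spatial regularization, no
  mixtures, no non-Gaussian tails. Heavy-tailed acquisition noise would
  inflate scores.
* The affine registration cannot remove anatomy-level deformation; on
  real data the atlas SD absorbs residual misalignment, widening the
  bounds near edges.
* Anomaly scores carry no semantic information: the pipeline locates
  "not normal" tissue but never names the pathology.
* Threshold calibration at observed extremes is sensitive to calibration
  outliers by design (one extreme normal scan raises
  $T_\text{upper}$); the safety margin mitigates only the lower side.
* Heatmaps live in atlas space; back-transformation to native scan space
  is out of scope.
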