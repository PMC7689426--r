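---
title: "Methods: texture-based outcome prediction for cardiac MR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based outcome prediction for cardiac MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cmrtexture)
```

This vignette is the package's own account of the models and procedures
it implements, the parameters that matter, the numerical conventions
chosen where the field leaves room, and what the synthetic cohort can
and cannot show about real data.

## The problem

Takotsubo syndrome (TTS) is an acute, usually reversible heart-failure
condition. Cardiac MR in the (sub)acute phase yields T2-weighted images
(sensitive to myocardial edema) and late-gadolinium-enhancement images
(sensitive to fibrosis/necrosis). The question the pipeline addresses
is whether quantitative texture of the left-ventricular myocardium on
these images carries prognostic information about a binary long-term
outcome (5-year MACCE), in a small cohort (tens of subjects, a handful
of events) where feature reliability across readers is as much a
concern as predictive signal.

The pipeline has four stages — preprocess, extract, select, evaluate —
plus a synthetic cohort generator that stands in for the non-public
patient data and turns every stage into testable code.

## Preprocessing

Texture statistics are comparable only on a common grid, so images are
resampled to a uniform in-plane resolution, 0.390625 mm/pixel by
default (a 200 mm field of view over a 512 matrix). Bilinear
interpolation on pixel centers is used; an image already at the target
is returned bit-identically, which makes resampling idempotent.
Polygonal ROIs are mapped to the resampled grid and re-rasterized
(pixel center inside the polygon, even-odd rule); masks are never
interpolated, which would blur the region boundary.

Grey-level normalization uses the ±3σ window: with μ and σ the mean and
standard deviation of the *in-ROI* intensities,
`level(v) = clamp(1 + floor((v − lo)/(hi − lo) · Ng), 1, Ng)` with
`lo = μ − 3σ`, `hi = μ + 3σ`. Values at or beyond the window clip to
the extreme levels. Ng is 64 (6 bits) for the co-occurrence and
run-length families and 16 (4 bits) for the gradient family. Two
consequences are load-bearing: the quantized image is invariant under
affine intensity maps `v → k·v + c` (k > 0), and any boundary change of
the ROI changes μ and σ and therefore *re-windows every pixel* — which
is exactly why poorly reproducible contours degrade feature
reliability.

Order of operations: raw intensities are resampled first, and
normalization/quantization happens on the resampled grid, so the window
statistics always describe the pixels actually analyzed. A constant ROI
(σ = 0) maps to level 1 everywhere with a warning rather than erroring,
so degenerate fixtures flow through. Masks below 16 pixels are
rejected; co-occurrence statistics on smaller regions are noise.

## The texture engine

All families operate on the masked, quantized image; the registry
(`default_registry()`, 282 descriptors) drives which are computed, and
panel size is a property of the registry, not a constant of the engine.

*Co-occurrence.* Ordered pixel pairs `(p, p + a·d)` with both ends
in-mask are accumulated symmetrically (each pair increments `(i, j)`
and `(j, i)`), distances a = 1…5, directions 0°, 45°, 90°, 135°. The
direction set is the canonical half of the eight neighbours; symmetric
accumulation covers the opposite half. Counts are jointly normalized
and the eleven classical Haralick statistics are computed per matrix.
Conventions chosen where definitions vary in the literature: natural
logarithm in all entropies with 0·log 0 ≡ 0; sum variance is the
variance of the `p_{x+y}` distribution about the *sum average* (the
often-cited form about the sum entropy is treated as the historical
typo it is widely considered to be); correlation of a single-level
(zero-variance) matrix is defined as 0. Features are kept per
direction and distance, not averaged, since direction-specific features
are the ones a reader would recognize (e.g. `GLCM.d4.a135.DifVarnc`).

*Run length.* Maximal runs of equal level along scan lines of the four
angles, truncated at mask boundaries (an out-of-mask pixel ends a run).
The five Galloway statistics are computed per angle; the fraction of
image in runs is run count over in-mask pixel count.

*Gradient.* Central differences on the 4-bit image, magnitude the
Euclidean norm, restricted to in-mask pixels whose four axial
neighbours are in-mask. Moments use excess kurtosis, and zero variance
defines skewness/kurtosis as 0.

*Autoregressive model.* The causal four-neighbour model
`v(p) = θ₁v(W) + θ₂v(NW) + θ₃v(N) + θ₄v(NE) + e` is fitted by least
squares on mean-centered levels over pixels with a complete causal
neighbourhood. Rank-deficient designs (e.g. translationally degenerate
images) take the minimum-norm solution via the SVD pseudoinverse; a
fully degenerate system returns θ = 0, σ = 0 with a warning. σ is the
root-mean-square residual.

*Wavelets.* An orthonormal 2D Haar transform is applied recursively to
the low-pass band of the largest dyadic square inside the mask bounding
box (centered in the box; raw intensities, as is usual for windowed
wavelet texture). Per scale, each sub-band energy is the mean squared
coefficient; Parseval's identity at scale 1 is asserted in the tests at
1e-8. Scales beyond the window return missing values, which propagate:
any feature missing for at least one subject is dropped before
selection rather than imputed.

## Reliability and redundancy selection

Each feature is measured under three segmentations: reader 1 read 1,
reader 1 read 2, reader 2. Two ICCs are computed per feature —
inter-reader (r1r1 vs r2r1) and intra-reader (r1r1 vs r1r2) — using the
two-way random-effects, absolute-agreement, single-measure form
ICC(2,1): readers are treated as random raters and systematic reader
offsets count against agreement, the conservative choice for a
reproducibility filter. A feature is dropped when *either* ICC is at or
below 0.6 (a feature must be reproducible both across and within
readers); 0.60 itself drops, 0.61 survives. Bands follow Landis–Koch:
(0.6, 0.8] substantial, (0.8, 1.0] excellent.

Redundancy pruning then sweeps the survivors in order of decreasing
mean ICC (ties by registry order) and keeps a feature iff its absolute
Pearson correlation with every already-kept feature is ≤ 0.8 — strictly
greater than 0.8 marks redundancy, so a pair at exactly 0.8 survives
whole. |r| is used rather than signed r: a sign-flipped copy of a
feature is just as redundant. Reliability-ranked greedy retention makes
the procedure deterministic and favours stable features; the
correlation matrix is computed on reader 1 read 1, and a zero-variance
feature is dropped as degenerate (the report records it with its own
verdict since it names no retained partner). Clinical covariates (age,
sex as 0/1, BMI) pass through selection exactly like texture features.

## Evaluation

Five classifiers are evaluated: a single-hidden-layer perceptron with
`floor((p + 2)/2)` hidden units (the cited convention reads the
"(attributes + classes)/2" rule as hidden *units*), a pruned
CART decision tree standing for the C4.5 family (cost-complexity
pruning at the cross-validated optimum; leaf sizes small enough for
rare-event cohorts), Gaussian naive Bayes (implemented in the package
and cross-checked against an independent reference in the tests),
a 500-tree random forest, and a linear-kernel support-vector
classifier.

Cross-validation is stratified 10-fold, seeded: subjects are shuffled
within class and dealt round-robin, so every training split keeps both
classes — with 6 events in 58 subjects an unstratified "random tenths"
split regularly produces event-free folds and undefined fold metrics,
which is why predictions are also pooled across folds before any
metric is computed. Pooled hard predictions give the confusion metrics;
pooled scores give the ROC AUC (midrank method, identical to
trapezoidal integration; ties contribute 1/2) and the precision-recall
area (trapezoid over attained thresholds). Both class orientations are
always reported, since with rare events the two orientations differ
drastically in every confusion metric while sharing the same AUC.
Confidence intervals are normal-approximation intervals (mean ± 1.96
sd, clamped to [0, 1]) over replicate cross-validations under
independent seeds (default 10): the replication-over-seeds design is
the package's choice of a defined, reproducible interval.

AUC pairs are compared with the Hanley–McNeil z test; the correlation
term for same-subject comparisons is estimated as the average of the
within-class Pearson correlations of the two classifiers' pooled
scores. Equal AUCs compare as z = 0 regardless of the standard-error
denominator. Per-feature group differences use a Mann–Whitney U test
with midrank ties; for n₁ + n₂ ≤ 12 the two-tailed p-value is exact by
enumeration of all labelings of the observed values (a permutation
null, so ties are handled exactly — the reason this is implemented
in-package rather than delegated to `wilcox.test`, which abandons
exactness under ties), otherwise a tie-corrected,
continuity-corrected normal approximation is used.

## The synthetic cohort

The generator emulates the study population: 58 subjects, exactly 6
events (10.3 %) and 56 women per cohort (fixed counts, randomized
assignment), age ~ N(68.4, 11.8²) years clipped to [30, 95], BMI ~
N(24.4, 4.3²) kg/m² clipped to [14, 45]. Images are 256×256 at
0.390625 mm — native resolution, so the resampling stage is an exact
identity on default cohorts. Each subject has an elliptical myocardial
ring (outer radius 55–70 px, thickness 18–26 px, mild eccentricity,
jittered center) between a dark background and a bright blood pool; the
base segmentation is a 24-vertex polygon tracing the outer boundary.

In-ring T2w intensities are a smooth Gaussian random field (white noise
smoothed by an isotropic Gaussian kernel, correlation length 3 px,
SD 60) plus white noise (SD 10). Event subjects get a longer
correlation length (+4 px) and higher field SD (+50): the prognostic
signal lives purely in T2w texture, by construction. These two effect
parameters are free in the emulated design (the source setting reports
no quantitative effect size); they were calibrated once so that the
default corresponds to a strongly prognostic cohort (pooled naive
Bayes AUC well above 0.85 on selected features) while
`effect_dell = 0, effect_dsd = 0` defines the null cohort, and they are
not adjusted thereafter.

LGE-like images carry no outcome effect. Their in-ring field is
high-frequency (correlation length 0.8 px, amplitude `lge_granularity`
= 120), with a bright epicardial collar just outside the true boundary
(fat is not suppressed on LGE). Re-segmentation instability is realized
by drawing each image's contours separately, with a larger radial
vertex jitter on LGE (5 px, vs 1.5 px on T2w) — motivated by the much
lower myocardium/background contrast a reader faces on LGE. This
specific mechanism matters: experiments during development showed that
in-ring granularity alone leaves global texture statistics almost
unchanged under small boundary jitter (inter-reader ICCs near 0.98),
because statistics over thousands of pixels concentrate; instability
has to enter through the contour and through intensity steps at the
boundary. With the default settings the reliability filter removes LGE
features preferentially, and ≥90 % of selection survivors are
T2w-derived across seeded cohorts — the qualitative headline of the
emulated study becomes a property of the synthetic ground truth.

Randomness is hierarchical: a master seed deterministically derives
per-stage, per-subject and per-fold sub-seeds (an integer hash below
2^31), so cohorts are bit-reproducible, covariates do not depend on
whether images are rendered, and stages can be replayed in isolation
from a run manifest.

What the generator does *not* emulate: cardiac anatomy beyond an
annulus, MR physics (no k-space, no bias fields, no motion), ballooning
morphology, inter-scanner variation, or any realistic relation between
demographics and outcome (covariates are drawn independently of the
label). Passing tests on synthetic cohorts therefore validate the
*pipeline's statistical machinery* — extraction correctness, filter
semantics, calibration of the evaluation protocol — not the clinical
claim that T2w texture predicts MACCE in patients.

## Numerical choices and degenerate inputs

- Entropies: natural log, 0·log 0 ≡ 0. Correlation of a zero-variance
  co-occurrence matrix: 0. Moments: excess kurtosis; zero variance ⇒
  skewness = kurtosis = 0.
- Quantization boundaries: `v ≤ lo ⇒ 1`, `v ≥ hi ⇒ Ng`; σ = 0 windows
  map everything to level 1 (warning).
- Rasterization: pixel center strictly inside by even-odd crossing
  counting; a center exactly on a crossing is resolved by the
  strict-right-ray convention, deterministically.
- ICC degenerate denominator (no between-subject variance): defined as
  0 with a warning, which the ≤ 0.6 filter then drops — the safe
  outcome for a feature that cannot distinguish subjects.
- Pooled cross-validation with a handful of events is known to be
  slightly pessimistic under the null (the event-class model is fitted
  on 5 rather than 6 events for exactly the folds that contain the
  held-out event); the null calibration band is therefore centred
  slightly below 0.5. This is a property of the protocol, quantified in
  the tests, not corrected away.
- Problem sizes used by the test suite: brute-force texture oracles on
  ≤ 8×8 images; ICC recovery at n = 58 with 500 replicates per true
  value; classifier calibration over 20 seeded cohorts per arm;
  selection-headline check over 20 cohorts; demographic targets over
  200 covariate-only cohorts. These sizes give Monte-Carlo error
  comfortably inside each asserted tolerance.

## Known limitations

- The panel is the 282-descriptor registry above; texture families not
  in it (Gabor, Laws, fractal) and 3D/multi-slice texture are out of
  scope, as are scanner harmonization beyond ±3σ windowing, bias-field
  correction and cine handling.
- DICOM input is not parsed; images enter as 16-bit PGM rasters with a
  plain-text spacing sidecar (or in-memory matrices), which is
  lossless for the pipeline's purposes.
- The MLP is fit with BFGS (`nnet`) rather than online backpropagation
  with a learning-rate/momentum schedule; the architecture rule and
  seeding are honoured, the optimizer is the R ecosystem's standard.
- `wilcox.test`-style exactness: the package's exact Mann–Whitney p is
  a permutation p over the observed values, which is exact under ties
  but quadratic-cost in the enumeration; it switches to the corrected
  normal approximation above n₁ + n₂ = 12.
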