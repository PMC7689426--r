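# cmrtexture

Radiomics texture analysis for outcome prediction on short-axis cardiac
MR images, built around the workflow used to study long-term prognosis
in takotsubo syndrome: texture features are extracted from a
left-ventricular region of interest on paired T2-weighted (T2w,
edema-sensitive) and late-gadolinium-enhancement (LGE,
fibrosis-sensitive) images, unreliable and redundant features are
removed, and the survivors feed cross-validated machine-learning
classifiers of a binary 5-year MACCE outcome (major adverse cardiac and
cerebrovascular events).

The package is aimed at imaging researchers who want the complete
pipeline — preprocessing, feature engine, reliability selection,
evaluation — as tested, reusable R functions, together with a fully
synthetic cohort generator so that every stage can be exercised and
validated without access to patient data.

## What it computes

**Preprocessing.** Images are resampled to a uniform in-plane
resolution (default 0.390625 mm, i.e. a 200 mm field of view over a
512 matrix) by bilinear interpolation; polygonal ROIs are re-rasterized
on the new grid (pixel centers, even-odd rule). In-ROI intensities are
windowed to μ ± 3σ and quantized to Ng = 2^b grey levels (b = 6 for
co-occurrence and run-length families, b = 4 for the gradient family),
making all downstream features invariant to affine intensity maps
v → k·v + c.

**Texture engine** (282 features per ROI, data-driven registry):

- histogram: mean, variance, skewness, kurtosis;
- grey-level co-occurrence matrix (GLCM), symmetric and jointly
  normalized, at distances a = 1…5 and directions 0°/45°/90°/135°:
  the eleven classical Haralick statistics per matrix (angular second
  moment, contrast, correlation, sum of squares, inverse difference
  moment, sum average, sum variance, sum entropy, entropy, difference
  variance, difference entropy; natural log, 0·log 0 ≡ 0);
- run-length matrix (RLM) at four angles: short/long-run emphasis,
  grey-level and run-length non-uniformity, fraction of image in runs;
- absolute gradient (central differences on the 4-bit image): mean,
  variance, skewness, kurtosis, fraction of non-zero gradients;
- causal autoregressive model v(p) = θ₁v(W) + θ₂v(NW) + θ₃v(N) +
  θ₄v(NE) + e, fitted by least squares: θ₁…θ₄ and the residual σ;
- orthonormal Haar wavelet energies (LL/LH/HL/HH) at up to 7 scales on
  the largest dyadic square inside the ROI bounding box.

**Selection.** Each ROI is segmented three times (reader 1 twice, two
weeks apart in the emulated design, and reader 2 once). Features with
inter- or intra-reader ICC(2,1) ≤ 0.6 are excluded; the survivors are
greedily pruned so that no kept pair has Pearson |r| > 0.8, visiting
features in order of decreasing mean ICC.

**Evaluation.** Stratified, seeded 10-fold cross-validation of five
classifiers (multilayer perceptron, pruned decision tree, Gaussian
naive Bayes, random forest, linear-kernel SVM), predictions pooled over
folds; sensitivity, specificity, precision, recall, F-measure, ROC AUC
(rank method) and precision-recall area, in both class orientations,
with confidence intervals over replicate seeds. AUCs are compared with
the Hanley–McNeil standard error
SE² = [A(1−A) + (n₊−1)(Q₁−A²) + (n₋−1)(Q₂−A²)]/(n₊n₋),
Q₁ = A/(2−A), Q₂ = 2A²/(1+A), and per-feature group differences with a
Mann–Whitney U test (exact by enumeration for small samples).

**Synthetic cohort.** 58 subjects (56 female, mean age 68.4 ± 11.8 y,
BMI 24.4 ± 4.3 kg/m²) with exactly 6 events (10.3 %); per subject, a
256×256 T2w-like and LGE-like image of an elliptical myocardial ring
plus blood pool, and per image three reader polygons. A tunable texture
effect (longer correlation length and higher variance of the in-ring
Gaussian random field) is injected only into T2w images of event
subjects; LGE re-segmentation instability comes from a granular
high-frequency field, a bright epicardial collar at the boundary, and
larger LGE contour jitter.

## Worked example

```r
library(cmrtexture)

run <- run_pipeline(run_config(seed = 1))   # simulate -> extract -> select -> evaluate
write_report(run)
```

The report starts with the selection outcome (seed 1):

```
== Texture pipeline run ==
subjects: 58 (6 events)
features entering selection: 559
dropped by reliability (ICC <= 0.60): 254
dropped as redundant (|r| > 0.80): 281
kept: 24
```

Of the 559 complete features (two sequences plus age, sex, BMI), 254
fail the ICC filter — predominantly LGE-derived, because the granular
LGE appearance makes repeated contours much less reproducible — and 281
more are redundant, leaving 24 (21 of them T2w-derived). The naive
Bayes block then reads:

```
NaiveBayes (positive class = 1):
  sensitivity  0.867 [0.729-1.000]
  specificity  1.000 [1.000-1.000]
  precision    1.000 [1.000-1.000]
  recall       0.867 [0.729-1.000]
  f_measure    0.927 [0.852-1.000]
  auc          1.000 [0.998-1.000]
  prc_area     0.997 [0.981-1.000]
```

i.e. on this synthetic cohort the injected T2w effect is strong enough
that pooled cross-validation recovers the event class almost perfectly;
a null cohort (`cohort_spec(effect_dell = 0, effect_dsd = 0)`) scatters
around chance instead (see `calibration_auc()`). The report ends with
Hanley–McNeil comparisons of every classifier against the top-AUC one.

A command-line wrapper with `simulate`, `run-all` and `report`
subcommands is installed at `inst/cli/cmrtexture.R`.

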