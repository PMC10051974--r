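---
title: "Superpixel-based tumor segmentation of TMA images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Superpixel-based tumor segmentation of TMA images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A digitized tissue-microarray (TMA) core is a square color image — around
6000 × 6000 pixels — showing a circular disc of stained tissue on a light
gray background. Pathologists mark tumor regions on such images by hand;
`tmaseg` automates the three-way segmentation of each core into **tumor**
(class code 2), **non-tumor tissue** (code 3) and **background** (code 0).
Code 1 is deliberately unused: the three-code set mirrors the labeling
convention of expert-marked TMA data, where labels are stored as 8-bit
rasters whose histogram contains exactly those three values.

Rather than classifying individual pixels, the method works at the level
of *superpixels* — contiguous groups of pixels with similar color — which
capture the redundancy of histological texture and cut the problem size by
three orders of magnitude. Segmentation then becomes supervised
classification of superpixels, and the segmented image is reassembled by
painting each superpixel with its predicted class.

## Pipeline

1. **Rescale.** Native cores are downscaled (default factor 0.25, giving
   roughly 1500 × 1500) by bilinear interpolation. Superpixel-level texture
   statistics are insensitive to this reduction while compute drops
   16-fold.
2. **Enhance.** One of three transforms is applied per image:
   *contrast normalization* (quantile stretch), *histogram equalization*,
   or *histogram matching* against a reference image. The pipeline
   compares all three (plus "none") and keeps the best.
3. **SLIC superpixels.** Localized k-means over combined color + position,
   governed by a grid size `S` (default 30 px) and a regularization
   `r` in [0, 1] (default 0.20).
4. **Features.** Each superpixel is described by 69 numbers: 17
   first-order histogram statistics and 6 Tamura texture features per RGB
   channel (23 × 3).
5. **Ground truth.** Expert tumor polygons (ImageJ `.roi` files) are
   rasterized to three-class label images; each superpixel receives the
   class of the plurality of its member pixels (majority vote).
6. **Learning and evaluation.** Five classifier families are compared
   under leave-one-image-out cross-validation on every enhancement, using
   per-class precision/recall/F1 and multiclass accuracy; the best
   (enhancement, classifier) pair is retrained on all images and used to
   segment them.

## Models and key formulas

**SLIC.** Cluster centers start on a regular `ceiling(H/S) × ceiling(W/S)`
grid. Each pixel joins the nearest center within a 2S × 2S window under

    D = d_color + (m / S) · d_xy,      m = 40 · r,

where `d_color` is the Euclidean distance in an opponent color space
obtained from RGB by a fixed orthonormal transform (intensity, red–green,
yellow–blue axes; a switch allows plain RGB), and `d_xy` the Euclidean
pixel distance. The mapping `m = 40 · r` makes `r` span "very elastic"
(r = 0) to "almost square" (r = 1) superpixels on 8-bit data; 40 is a
single documented constant. Ten assign/update sweeps are run — a fixed
iteration cap keeps the procedure deterministic and its cost predictable;
both the cap and the color space are configurable. Afterwards,
4-connectivity is enforced: detached fragments smaller than `S²/4` are
merged into the largest *adjacent superpixel*. Merging proceeds smallest
fragment first and only ever into a real superpixel, peeling inward, so
orphan fragments cannot coalesce into spurious detached superpixels;
detached components of at least `S²/4` pixels survive as superpixels of
their own. Superpixel ids are `1..K`, following the R indexing convention.

**First-order statistics (17).** mean, population variance, standard
deviation, skewness, excess kurtosis, energy (mean squared intensity),
RMS, Shannon entropy (base 2 over the 256 intensity bins), min, max,
median, range, mean absolute deviation, 25th/75th percentiles (type-7
quantiles), IQR, and coefficient of variation. Conventions for degenerate
regions: skewness and kurtosis are 0 when the variance is 0, and CV is 0
when the mean is 0, keeping every descriptor finite on any 8-bit input.
Only a subset of these statistics is canonical in the texture literature;
the full list of 17 is frozen in the package's feature-name registry
(`tma_feature_names()`) so that tables are comparable across runs.

**Tamura features (6).** Computed on the mask's bounding-box crop with
non-mask pixels filled by the mask mean (this prevents texture of
neighboring regions from leaking into the descriptor of an
irregularly-shaped superpixel):

- *coarseness* — for scales `2^k` (limited to `2^k ≤ min(crop)/2`),
  difference of box averages at offset `2^(k-1)` horizontally and
  vertically; each pixel picks the scale maximizing the difference and
  coarseness is the mean best scale over the mask (1 for crops too small
  to support any scale);
- *contrast* — `σ / α₄^{1/4}` with `α₄ = μ₄/σ⁴` the kurtosis of the crop
  intensities (0 when σ = 0);
- *directionality* — 1 minus the normalized entropy of the 16-bin
  gradient-orientation histogram over pixels whose gradient magnitude
  exceeds the mask median; orientations come from central differences,
  folded to [0, π), with bin centers aligned to the axes so that the
  measure is exactly preserved under 90° rotations;
- *line-likeness* — mean double-angle cosine `cos 2(θ_p − θ_q)` between a
  selected pixel's orientation and that of the pixel 4 steps along its
  gradient direction (double angle respects the π-periodicity of
  orientations);
- *regularity* — 1 minus the mean normalized dispersion (SD over mean
  magnitude, clipped at 1) of the first four features across the 2 × 2
  quadrant partition of the crop; defined as 0 when the crop is smaller
  than 8 × 8;
- *roughness* — coarseness + contrast.

**Metrics.** Per class (one-vs-rest): `PPV = TP/(TP+FP)`,
`TPR = TP/(TP+FN)`, `F1 = 2TP/(2TP+FP+FN)`, each 0 when its denominator
is 0. Multiclass accuracy is `correct/N`. The F-measure averaging method
is macro (unweighted mean over classes) because per-class F1 is defined
one-vs-rest; support-weighted F1 is reported alongside.

**Cross-validation.** One fold per image: train on all other images'
superpixels, test on the held-out image. Image-level folds prevent
within-image leakage (superpixels of one image share staining and
illumination); with 10 images the protocol coincides with classical
10-fold CV where each training set holds 9 images.

## Classifiers

The five families are analogues of the classical Weka line-up, built on
the standard R implementations where one exists: random forest
(`ranger`, 100 trees, √p features per split), SVM (`e1071`/libsvm, RBF
kernel, features standardized within the fit), a C4.5-style
entropy-split pruned tree (`rpart` with information splitting), naive
Bayes with Gaussian conditionals (`e1071`) as the minimal Bayesian
network, and LogitBoost. LogitBoost (additive logistic regression with
depth-1 regression stumps, one-vs-rest for multiclass, 30 iterations,
working responses clipped at ±4) is implemented in the package since no
installed package provides it. They are analogues, not bit-compatible
replicas; all training randomness flows from the seed in
`classifier_spec()`. Whether features should be standardized before the
SVM is not prescribed anywhere; the package standardizes for the SVM only
(inside `e1071::svm`), fitted on training folds only.

## Ground truth construction

The expert marking gives tumor polygons only; the other two classes are
derived photometrically. Background is defined as pixels brighter than an
Otsu threshold (computed per image on the grayscale mean) *and* with
channel spread `max − min < 20` — i.e. light *gray*, which distinguishes
bright background from bright pink tissue. Tumor is every non-background
pixel inside any polygon (even-odd fill, boundaries inclusive, so the
rasterization is bit-exact and reproducible); the background rule takes
precedence inside polygons. Everything else is non-tumor. Vote ties in
the majority assignment break by the fixed priority tumor > non-tumor >
background, biasing toward sensitivity in a diagnostic-support setting;
the priority is configurable.

A note on the majority vote: with three classes the plurality class of a
superpixel can cover less than half of its pixels. What the quantized
(superpixel-resolution) ground truth guarantees is that no other
superpixel-constant labeling agrees with the pixel labels on more pixels,
and that at least a third of each superpixel agrees; the package's tests
check exactly this property.

## The synthetic TMA generator

Real marked TMA sets are scarce, so the package ships a generator whose
output exercises every stage: a square image with a centered circular
tissue disc (radius 0.45 × size) on a light-gray background (level 220
with shared-luminance noise SD 3 — shared across channels so background
stays achromatic, satisfying the background chroma rule); smooth pinkish
non-tumor tissue (RGB 205/165/175, smoothed noise SD 8); and brown,
heavily speckled tumor (RGB 150/100/60, i.i.d. speckle SD 35). Tumor
regions are the super-level set of a smoothed Gaussian random field with
`n_tumor_blobs` (default 4) Gaussian bumps at random sites inside the
disc, thresholded at the in-disc quantile matching the target tumor
fraction (default 0.35) — so boundaries are irregular like real tumor
margins and the achieved fraction is within sampling ties of the target.
Labels are exact by construction. Class colors and noise levels were
chosen once so that first-order statistics alone separate the classes —
the mean channel gap between tumor and non-tumor is several times the
non-tumor within-class SD — making classifier recovery a property of the
method rather than of a particular learner.

What the generator does *not* emulate: nucleus-level morphology, stain
variation across cores, marker-specific chromogen distributions, focus
artifacts, and annotation noise. Passing the recovery tests therefore
shows the pipeline is wired correctly and that its descriptors separate
texture-distinct classes; it does not certify performance on real stained
tissue.

## Numerical choices

- All intensity quantization rounds half-up (`floor(x + 0.5)`); stated
  once and tested.
- The contrast stretch uses type-1 (inverse-ECDF) quantiles, which makes
  it exactly idempotent; the default saturation 0.0035 follows the
  interactive enhance-contrast convention.
- Histogram equalization uses the classic cumulative mapping
  `out(v) = round((cdf(v) − cdf_min)/(N − cdf_min) · 255)`; constant
  channels are returned unchanged. Equalization acts per image — unlike
  normalization and matching it needs no data-set-level reference.
- Histogram matching inverts the reference CDF by the smallest intensity
  whose CDF reaches the target; matching an image to itself is exactly
  the identity. The reference defaults to the first image of the set
  (nothing distinguishes any other choice; configurable).
- Rescaling happens before enhancement by default (configurable); the
  two orders differ only marginally for the transforms involved.
- Degenerate inputs: images smaller than the SLIC grid collapse to a
  single superpixel with a warning; empty masks and empty pixel sets are
  errors.

## Problem sizes used in the shipped checks

The package's own end-to-end check runs the full protocol on 10 synthetic
images at size 512 (the generator default) with histogram equalization
and the random forest, asserting cross-validated mean accuracy and macro
F1 of at least 0.90; unit and property tests use 64–256 px images and
small in-memory fixtures. These sizes were chosen to keep the whole suite
in the minutes range on a single CPU while leaving every stage's behavior
observable at realistic superpixel counts (hundreds per image).

## Known limitations

- The 17-statistic first-order list completes a partially specified
  descriptor set; different KNIME/Weka-era implementations used slightly
  different lists, so absolute feature values are not comparable across
  toolchains (rankings of enhancement/classifier pairs are).
- Tamura features on very small superpixels (crops under 8 × 8) fall back
  to degenerate values (regularity 0, coarseness 1); classifiers tolerate
  this but the descriptors carry little signal there.
- The classifiers are analogues of the Weka originals, not replicas;
  absolute accuracies can differ from a Weka run even on identical
  feature tables.
- No post-processing removes small misclassified islands from the
  segmented image; island removal is a natural extension.
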