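---
title: "Ensemble pixel classification for coronary vessel segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble pixel classification for coronary vessel segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

X-ray coronary angiography (XCA) projects contrast-filled coronary
arteries onto a 2-D detector. Downstream quantitative analysis — lumen
measurement, stenosis grading — needs a binary vessel mask, but XCA
frames are noisy, unevenly illuminated, and crowded with vessel-like
confounders (the dye catheter, spine and rib shadows). Vessel pixels are
also rare: they typically occupy only around 5–6% of a frame, so a naive
classifier that predicts "background" everywhere is already 94% accurate
and useless.

`vesselforge` treats segmentation as per-pixel classification. Each pixel
receives a feature vector summarizing how the image responds to a bank of
vessel-sensitive filters across physical scales, optionally augmented with
activation maps from a small segmentation network; a gradient-boosted tree
ensemble (or a cascade forest) then scores each pixel, and morphological
post-processing turns the score map into a clean mask.

## Physical scale anchoring

Every length in the pipeline is expressed in units of the dye catheter's
projected diameter (`cath_px`, "Cath"), which is known per frame from
acquisition metadata and has a population mean of 8 pixels (used as the
default whenever metadata is absent). Filter scales form a geometric
sequence from `0.66 * cath_px` to `6.33 * cath_px` — the calibre range of
coronary arteries relative to the catheter. The number of scales defaults
to 10; the endpoints are fixed by `build_scale_set()` and spacing is exactly
logarithmic, so consecutive scales share a constant ratio.

## The Z-profile

A filter applied at a single scale captures vessels of one calibre only.
Instead of selecting a best scale, each filter's per-pixel responses across
the scale set are summarized by four statistics — maximum, mean, variance,
and interquartile range (`zprofile()`). Two conventions are fixed for
reproducibility because their alternatives would change feature values:

* variance is the population variance (divide by the number of scales);
* quartiles use linear interpolation between order statistics (R's default
  type 7), so the IQR of responses `1,2,3,4` is exactly 1.5.

## Preprocessing

1. **Border exclusion.** The collimator frame is detected as the
   near-constant connected region touching the image edge
   (`exclude_border()`); border pixels never enter sampling or evaluation.
2. **Denoising.** Non-local means with patch width 5, search window 11,
   and filtering strength `0.8 *` the noise level estimated by Immerkaer's
   Laplacian method. These values are conventional for this filter family;
   they are exposed as arguments.
3. **Contrast enhancement.** Multi-scale top/bottom-hat:
   `I + m * I_top - n * I_bottom`, where `I_top`/`I_bottom` are the maxima
   over the scale set of opening/closing residues with disc structuring
   elements of diameter equal to the scale. Discs are used because they are
   rotation-invariant, matching curved vessels. The strengths default to
   `m = n = 1`: equal weight to brightening the background and deepening
   dark vessels; both are configurable.
4. **Vesselness-enhancing diffusion.** An explicit anisotropic scheme
   (default 5 iterations, time step 0.15) whose tensor has unit
   conductivity along the local Hessian vessel direction and
   `0.05 + 0.95 * (1 - v)` across it, with `v` the dark-ridge Frangi
   response at the geometric mid-scale. Five iterations measurably raise
   the contrast-to-noise ratio along synthetic tubes without rounding
   corners; the scheme is stable for time steps up to 0.25.

## The 21 filter features

* **Frangi Z-profile (4).** Hessian eigenvalue vesselness at sigma =
  scale/2, gamma-2 normalized, dark-vessel polarity (`lambda_2 > 0`),
  blobness sensitivity `beta = 0.5`, and structural constant set per image
  and scale to half the maximal Hessian norm.
* **Matched filter Z-profile (4).** Twelve orientations (15 degree steps)
  of a zero-mean, unit-energy negated-Gaussian cross-profile (sigma =
  scale/3, length 3x scale); per scale the orientation maximum is kept.
  Unit-energy normalization makes responses comparable across scales, which
  the Z-profile max requires.
* **Smoothed gradient magnitude Z-profile (4).** Gaussian-derivative
  gradients at sigma = scale/2.
* **Vessel confidence (1).** The orientation- and scale-maximal normalized
  correlation between the locally standardized image and the matched
  profile, clipped to [0, 1]. This is a contrast-invariant agreement score
  between the local cross-section and an ideal vessel profile; it shares
  the matched filter bank, so it costs no extra convolutions.
* **Granulometric Z-profile (4).** Differences of openings at consecutive
  scales of the enhanced image (the first residue is taken against the
  image itself), isolating bright granules by size class. Bright residues
  are used because enhancement brightens the vessel surround; a
  closing-based dark-granule variant would be symmetric but redundant with
  the bottom-hat content already in the enhanced image.
* **Gabor Z-profile (4).** Twelve orientations of DC-corrected real Gabor
  kernels (wavelength = 2x scale, envelope sigma = 0.56x wavelength, unit
  aspect ratio) on the complement of the enhanced image, where vessels are
  bright; orientation maximum per scale.

The differentiable domain therefore holds 13 maps (4+4+4+1), the spatial
domain 4, and the Gabor domain 4 — 21 filter-based features, plus 16 deep
maps for the full 37.

## Deep features

A compact encoder–decoder (one 8-channel conv stage, 2x mean-pool,
16-channel bottleneck, nearest-neighbour upsampling with a skip
connection, a final 16-channel decoder conv, and a 1x1 sigmoid head) is
trained from scratch on synthetic pairs with the generalized Dice loss,

GD = 1 − 2 Σ_c w_c Σ_p G_cp M_cp / Σ_c w_c Σ_p (G_cp + M_cp),
w_c = ((Σ_p G_cp / t)² + ε)⁻¹, t = 2, ε = 1e-8,

whose inverse-squared-volume weights counter the vessel/background
imbalance. Training follows a fixed recipe: Adam at 1e-3, batches of 8, at
most 100 epochs, early stopping after 15 epochs without validation
improvement, and paired affine augmentation (rotation within ±20 degrees,
shifts up to 10% per axis, zoom up to 10%) applied with probability 0.7.
Inputs are min/max normalized per image. The 16 activation maps of the
final decoder layer, extracted by a pure forward pass, are the deep
features; the deep path is optional and the pipeline runs in 21-feature
mode without a checkpoint.

The backbone is deliberately small: it trains on a CPU in minutes at desk
scale and preserves only the 16-channel final-decoder contract that the
feature stack consumes. It is not a reimplementation of any large
pretrained segmentation backbone, and its absolute segmentation quality is
irrelevant beyond providing informative features.

## Under-sampling cascade

Vessel pixels are ~5.6% of a frame and neighbouring pixels are highly
correlated, so training on all pixels overfits and wastes time. Four
stages, each auditable via `build_report()`:

1. **Uniform.** Background pixels are thinned to a stride-2 lattice whose
   phase is deterministic per image, so no two retained negatives are
   8-neighbours; the retained fraction is bounded by 25%. Positives are
   untouched.
2. **Unsupervised (intensity).** The enhanced image's 256-bin histogram is
   median-filtered (width 5 bins — wide enough to flatten a single-bin
   spike, narrow enough to preserve the modes); the bin where the raw pdf
   most exceeds the smoothed pdf is the enhancement-induced saturation
   peak. The median intensity outside that peak is the threshold: retained
   negatives brighter than it are certain background and are dropped. The
   image-wide bright mask is kept and reused at post-processing time.
3. **Tomek links.** Mutually nearest neighbour pairs with opposite labels
   (standardized Euclidean features) are removed — both members, from both
   classes. Removal is iterated until a rescan finds no links, so the
   output is link-free and the operation idempotent; the classic single
   pass is available as an option. Nearest neighbours are maintained
   incrementally (only points whose neighbour vanished are rescanned), so
   later passes are cheap.
4. **Cluster centroids.** Each class is replaced by a fixed number of
   k-means centroids (Lloyd, capped iterations), yielding an exactly
   balanced 50/50 set of synthesized rows. Applied per image at 4,000 per
   class, 104 training frames yield exactly 832,000 rows.

The uniform and intensity stages are inherently per image. The supervised
stages are also applied per image here: the per-image-then-pool order keeps
the 2 x 4,000 x images row arithmetic exact and bounds the nearest-neighbour
working set by the image size, at the cost of never removing cross-image
links — immaterial, since links encode local feature-space overlap that is
equally visible within images.

## Classifiers

Features are standardized per map with training-set means and standard
deviations; the saved parameters transform validation and test data
unchanged, including inside every tuning fold.

* **GBDT** (via `xgboost`): binomial deviance objective, tuned over
  learning rate {0.01, 0.05, 0.1}, boosting stages {100, 500, 1000, 2000},
  and depth {3, 5, 10, 20} by 4-fold cross-validation at the image level.
  Folds are built by ordering the training images (a seeded shuffle),
  cutting four contiguous blocks, and rotating which block validates — a
  cyclic 3:1 composition. The winner maximizes the mean validation AUROC,
  computed on pixels pooled within each fold (pooling reduces the variance
  of the fold estimate relative to per-image averaging over few images).
* **Cascade forest**: layers of 2 random forests + 2 completely-random
  forests (extra-trees with one random split variable), each layer
  consuming the original features plus the previous layer's 8
  class-probability columns; depth grows while 3-fold internal accuracy
  improves, capped at 4 layers. Run with defaults, untuned, as cascade
  forests are designed to be.

Data are split 4:1 at the image level, stratified by view (LCA/RCA) and
source; the test images coincide exactly with the deep-learning split's
test fifth (the ensemble training set is the union of the deep train and
validation sets), so no image ever informs both a feature extractor and
its own evaluation.

## Post-processing and evaluation

Probability maps are binarized with Otsu's method (256-level exhaustive
between-class-variance search; ties break toward the lower threshold),
then cleaned: border pixels forced to background, pixels of the
unsupervised background mask forced to background (they were excluded from
training as certain background, so restoring them as candidates would
contradict that rationale), and 8-connected components under 50 pixels
removed (8-connectivity matches diagonal vessel steps; it is configurable).

Metrics are precision, sensitivity, specificity, F1, IoU and AUROC,
computed image-wise over in-border pixels and reported as mean ± sd over
test images. AUROC uses the pre-binarization probability map — the only
information-bearing choice — via the rank statistic with half-credit ties.
A metric with a zero denominator is reported as `NA`, never as zero, so
image-wise averages are not silently biased. Permutation importance
shuffles each feature column 10 times on held-out pixels and reports the
mean increase in squared-error criterion over the unpermuted baseline.

## The synthetic generator

The study's clinical frames are private, so `generate_dataset()` emulates
their statistical structure: 512 x 512 gray-scale frames; a connected
vascular tree of dark tubes with inverted-Gaussian cross-sections (FWHM
equal to the local diameter, depth increasing with calibre) rooted at a
frame edge; diameters spanning 0.3–2x the catheter diameter with strict
parent-to-child tapering; per-frame catheter diameters drawn from a
positive-truncated Normal(8.0, 1.2); LCA/RCA labels at the 80:130 clinical
ratio; and an annotation rule that masks only vessels at least
0.75 x Cath wide, so the thinnest rendered twigs are deliberately
unlabelled, as in the clinical protocol. The annotated vessel fraction is
driven to a 5.6% target (the clinical mean share) by rescaling diameters
against the rasterized mask, with re-rasterization to absorb junction
overlap; across frames the realized fractions spread naturally with tree
geometry. Confounders make naive thresholding fail: a straight
catheter-width tube of low contrast, two to three broad soft vertical
bands imitating spine and rib shadows, a planar illumination gradient, and
additive Gaussian noise (sigma 0.03 of the intensity range). A 6-pixel
dark collimator frame defines the border mask.

What the generator does **not** emulate: quantum and structured detector
noise, motion blur, foreshortening, vessel overlap from projection,
contrast washout dynamics, and pathology (stenoses, aneurysms). Passing
tests on these synthetics therefore demonstrates that the pipeline's
machinery is correct and that its learning stages beat a single-feature
baseline under controlled conditions — not clinical-grade performance.

## Problem sizes and numerical choices

The test-suite and the acceptance script exercise the pipeline at sizes
chosen to keep a full run on one CPU comfortable: bookkeeping runs use the
full 130-frame, 512 x 512 study geometry with a 2-feature representation
for the sampling audit (the cascade's row arithmetic is independent of
feature dimension) and a k-means iteration cap of 2; the end-to-end
segmentation runs use 20 frames at 256 x 256 with `cath_px = 4`,
mirroring a 2x downsampled clinical frame, with the 21-feature stack and
the uniform + intensity + Tomek cascade. Degenerate inputs are handled
explicitly: constant images keep all negatives at the intensity stage
(with a warning), zero-variance feature maps standardize to zeros,
constant probability maps binarize to all-background, and single-class
inputs make Tomek removal the identity and AUROC undefined.

## Known limitations

* The vessel-confidence measure is a normalized-correlation agreement
  score designed to the same contract (a [0, 1] profile-agreement map);
  published variants of such measures differ in detail.
* FFT-based filtering with replicate padding introduces no wrap-around
  but does assume the frame's edge statistics extend outward; with the
  collimator border excluded this is harmless.
* Tomek-link removal above a few hundred thousand pooled pixels becomes
  memory-bandwidth bound; the per-image cascade order keeps it bounded.
* The generator's realism limits are listed above; no claim transfers to
  clinical data without retraining and re-evaluation on real frames.
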