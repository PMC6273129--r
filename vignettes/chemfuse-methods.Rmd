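---
title: "Methods: multivariate fusion of paired chemical images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate fusion of paired chemical images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemfuse)
```

## The problem

Two vibrational-spectroscopic microscopes image the same sample area and
produce two chemical image cubes: 3-D arrays (rows x cols x bands) in which
every pixel holds a full spectrum. The modalities see complementary
chemistry (a vibration that is strong in infrared absorption may be weak in
Raman scattering and vice versa), their pixel sizes differ (for the default
geometry here, 25 um versus 6.2 um — deliberately not a whole-number
multiple), and the fields of view are rotated, flipped and slightly offset
relative to one another. `chemfuse` implements the full workflow that turns
such a pair into joint information: registration onto a common pixel grid,
three levels of data fusion with pixel classification, co-inertia analysis
of the shared structure, band-to-band correlation mapping, cross-modality
regression, and spatial resolution enhancement.

## Registration

Registration proceeds in five steps, all driven by the data themselves
rather than by external fiducials:

1. **PCA per cube.** Each cube is unfolded to a (pixels x bands) matrix,
   mean-centered, and decomposed by SVD. One principal-component score
   image per modality is chosen as the registration target — the component
   in which the salient common feature (e.g. a drawn marker loop) is most
   visible. Which component that is differs by modality and is a user
   choice (`pc_low`, `pc_high`).
2. **Thresholding.** The score images are converted to binary masks by
   Otsu's histogram method (256 bins, between-class variance maximised).
   The mask polarity is normalised so that the minority phase is
   foreground. Thresholding can be disabled (`threshold = "none"`) for
   samples where it destroys the feature, e.g. resolution test targets.
3. **Orientation and resize.** The high-resolution target is rotated by
   quarter turns, flipped, and down-sampled to the low-resolution grid by
   separable bicubic interpolation (Keys kernel, a = -0.5) with kernel
   dilation when down-sampling (antialiasing). Down-sampling the sharp
   image — rather than up-sampling the coarse one — best represents what
   both instruments saw. Orientation is a user hint, with an optional
   exhaustive search over the 8 dihedral orientations scored by
   post-registration mean square difference.
4. **Affine optimisation.** A 6-parameter affine transform (translation,
   rotation, anisotropic scale, shear; `dof = "similarity"` restricts to
   4) is fitted by minimising the mean square difference between the fixed
   mask and the bilinearly warped moving mask, using regular-step gradient
   descent: normalised-gradient steps of fixed length that halve whenever
   the gradient direction reverses (defaults: maximum step 0.0625, minimum
   step 1e-5, relaxation 0.5, 300 iterations per run). Coordinates are
   pixel centers with the origin at the image center; translation
   parameters are rescaled by half the image extent so all six parameters
   live on one scale.
5. **Slice-wise application.** The orientation, resize and affine are
   applied to every band of the high-resolution cube, giving a registered
   cube whose pixels match the low-resolution grid; out-of-view pixels are
   flagged in the bad-pixel mask.

Three robustness measures were added after studying the optimiser's
behaviour on phantoms. First, the metric is evaluated only over in-view
pixels, which also makes it exactly invariant to adding a constant to both
images. Second, the fit runs in two stages — similarity first, then the
full affine initialised from it — because the 4-parameter problem is much
better conditioned and leaves the shear/anisotropy parameters a short
distance to travel. Third, the descent is restarted (twice by default)
from the best point found with the step length reset: the fixed-length
step otherwise collapses prematurely when the descent path crosses a
narrow valley. Both target images are smoothed with a 1-pixel Gaussian
before optimisation to widen the capture range of the metric on binary
masks. With these measures the recovered transform lands within half a
low-resolution pixel of ground truth on essentially every phantom draw; a
plain single-stage descent missed rotation by several degrees on a
substantial fraction of draws.

## Preprocessing

* **Bad pixels.** Detector faults are found by comparing each pixel's
  summary statistics (median intensity, log spectral variance) with the
  median of its 3x3 neighbourhood; a pixel is flagged beyond
  `z_threshold` (default 5) robust z-units, where the scale is the MAD of
  the residual image floored at 5% of the statistic's dynamic range. The
  floor encodes the position that detector faults are gross outliers:
  without it, the MAD of a very quiet residual image is so small that
  legitimate smooth-field curvature is flagged. Dead pixels (zero spectral
  variance) are always flagged. On samples with strong sub-resolution
  structure (sharp boundaries thinner than a pixel) boundary pixels can
  legitimately exceed the threshold; raise it or mask manually in such
  cases.
* **Savitzky-Golay second derivative** (window 15, polynomial order 3 by
  default) suppresses baseline and morphology effects. The filter is exact
  for polynomials up to the fitting order; output is trimmed to the bands
  where the full window fits ((window-1)/2 bands lost at each end), so no
  boundary derivatives are fabricated.
* **Scaling before fusion.** Each unfolded block is autoscaled per band
  (mean 0, sample standard deviation 1 with the n-1 denominator), then
  divided by the square root of its band count ("block scaling", which
  equalises the total variance of autoscaled blocks so the modality with
  more bands cannot dominate), then divided by its maximum absolute value
  ("maximum scaling"). The order — autoscale, block, maximum — follows the
  order in which the steps are conventionally described; all parameters
  are stored and invertible.

## Fusion and classification

* **Low-level**: the scaled blocks are concatenated along the band axis.
* **Mid-level**: PCA is run per modality and the leading score images
  (default 10 + 10) are concatenated; this inherits PCA's noise filtering.
* **High-level**: PLS-DA classifiers run per modality and their class maps
  are merged by consensus — agreeing pixels keep their class, disagreeing
  pixels become *unknown* (0).

Classification is PLS2 discriminant analysis on unfolded data: a one-hot
indicator matrix is regressed on the spectra and a pixel takes the class
with the maximum predicted response (ties broken deterministically toward
the lowest class index). The image is split at the vertical midline into a
model-building half and a held-out half; the model-building half is
sub-split into calibration (odd pixel rows) and validation (even rows,
interleaved). The latent-variable count is the smallest one whose
validation global percent-correct is within 0.5 percentage points of the
maximum — the criterion is the global percent correct, the 0.5-point band
is the tie rule. Global accuracy counts unknown predictions as wrong,
which is why consensus fusion, whose whole point is to flag disagreement,
scores below its inputs on that metric while being more trustworthy where
it does commit.

The trilinear (pixels x bands x modality) variant of PLS-DA is out of
scope; all models here operate on unfolded two-way matrices.

## Co-inertia analysis

Given column-centered blocks `X_k` over the same pixels, each component is
the dominant singular triplet of the concatenated matrix: the unit global
loading `u` and global score `s = X u`. Block loadings `u_k` are the
partition of `u` over the band ranges, block scores are `s_k = X_k u_k`,
and after each component every block is deflated by regression on the
global score. Deterministic sign: the largest-magnitude element of each
global score is positive. Three similarity metrics quantify block sharing:

* loading contribution `100 ||u_k||^2 / ||u||^2` — sums to exactly 100
  over blocks because `u` has unit norm;
* component contribution `100 cov^2(s_k, s) / sum_k var(s_k)^2` — does
  *not* sum to 100; its magnitude depends on the block scaling in use, and
  the bracketing of the denominator is one reading of an ambiguous
  convention, so it is isolated in a single function
  (`block_component_contribution`) for easy revision;
* Pearson correlation between `s_k` and `s`.

With a single block the procedure reduces exactly to PCA; with two
identical blocks every block-global correlation is 1 and the loading
contributions are 50/50 — both are tested, along with agreement to 1e-8
with a dense SVD oracle that performs the deflation explicitly.

## Correlation mapping and cross-modality prediction

The correlation map is the matrix of Pearson correlations between every
band of one registered cube and every band of the other; band pairs beyond
a threshold (default 0.85) are reported individually and as contiguous
band ranges. Which spectral representation feeds this analysis is a user
choice; the preprocessed (second-derivative, scaled) form is the default
recommendation since raw intensities correlate through baseline as much as
through chemistry.

PLSR prediction regresses one modality's bands on the other's spectra over
registered pixels. Rows are partitioned deterministically by row index
modulo 3 into calibration (fit), validation (model-order selection) and
test (never touched during selection). The latent-variable count is the
smallest with validation RMSE within 2% of the minimum — a parsimony rule
standing in for more elaborate order-selection schemes, isolated in
`plsr_fit`. The relative error spectrum compares mean spectra:
`100 |mean_pred - mean_actual| / |mean_actual|` per band, with bands whose
actual mean is below `1e-12 x max|mean|` flagged undefined; a per-pixel
variant is available (`per_pixel = TRUE`). Bands that correlate poorly
across modalities predict poorly — the package's tests assert a rank
correlation above 0.8 between band correlation and negative relative error
on phantoms with mixed shared/private structure.

**Resolution enhancement** applies a PLSR model trained on the registered
(down-sampled) pair to the original high-resolution predictor cube,
yielding the predicted modality on the fine grid. Because the model was
trained on down-sampled (hence smoothed) spectra, the raw high-resolution
spectra are first PCA-denoised — reconstructed from their leading 10
components by default — before prediction.

## The phantom generator

No real instrument data ships with the package; every guarantee is
demonstrated on synthetic phantoms that reproduce the statistical
structure the methods assume:

* **Linear mixing**: noiseless signal = per-class concentration maps times
  per-modality pure spectra (sums of Gaussian peaks on each modality's
  axis). Concentrations are non-negative and sum to 1 per pixel.
* **Geometry**: background, an open tilted elliptical loop (the salient
  marker feature), and a central disk plus inclusions of unequal size. The
  loop is deliberately not a circle: a rotationally symmetric loop leaves
  the rotation angle nearly unconstrained in mask-based registration, a
  degeneracy no hand-drawn marker has.
* **Misalignment**: the high-resolution cube is affine-jittered about its
  center, then inversely oriented (quarter turns and flips), so that the
  exact recovering pipeline is known. The ground-truth affine on the
  low-resolution grid is the jitter inverse conjugated by the per-axis
  resize scaling. Landmark agreement between recovered and true pipelines
  is evaluated by pushing coordinate-ramp cubes through both — bilinear
  interpolation is exact on linear ramps, so this measures the transforms
  themselves.
* **Shared versus private structure**: a per-class weight in [0, 1] mixes
  the shared concentration map with an independent smooth field in the
  second modality, controlling cross-modality predictability band by band.
* **Complementary information**: optionally two classes are given
  identical pure spectra within one modality (and a different pair in the
  other), so each modality alone separates only 2 of 3 classes while their
  fusion separates all 3.
* **Noise and defects**: i.i.d. Gaussian band noise, optional per-row
  stripe noise (emulating linear-array detector artefacts), and injected
  hot/dead pixels, all added last; a single seed makes the phantom
  bit-reproducible.
* **Class labels**: the argmax of the concentration maps, with pixels
  whose dominant concentration is below 0.85 left unlabelled — at a mixed
  boundary pixel the "true" class is genuinely undefined, and a
  classification ceiling of 100% is only meaningful on pure pixels.

Default problem sizes: a 48 x 46 low-resolution grid at 25 um and the
corresponding 194 x 186 high-resolution grid at 6.2 um, 120 IR-like bands
(1000-1800 cm^-1) and 60 Raman-like bands (400-1800 cm^-1), noise sigma
0.01 against unit-scale peaks. These sizes keep a full 20-replicate
registration study around a minute while leaving every effect measurable.
The defaults for classes 2 and 3 share a dominant foreground peak per
modality so that the first principal component is a clean foreground
contrast in both modalities — the regime the registration strategy
targets; class-specific secondary peaks keep the classes separable.

What the phantoms do *not* emulate: physically meaningful band
assignments, scattering and optical effects, baseline drift, detector
nonlinearity, or spatially correlated chemical noise. Passing phantom
suites therefore demonstrates algorithmic correctness and the advertised
statistical behaviour, not instrument-grade performance on any particular
sample type.

A second generator builds resolving-power targets: binary bar triplets
(bar width = gap) or pairs of Gaussian spots 3 high-resolution pixels
apart (less than one low-resolution pixel), with the low-resolution cube
formed by exact block averaging. These drive the enhancement tests: the
spot pairs must appear as two local maxima in the predicted
high-resolution image and at most one in the low-resolution image.

## Numerical choices and degenerate inputs

* Pixel ordering on unfolding is row-major, 0/1-based per R convention,
  with an index map making refolding exact; excluded (bad) pixels refold
  to a caller-chosen fill value and stay masked.
* PCA uses the SVD of the mean-centered matrix with a deterministic sign
  convention (largest-magnitude loading element positive).
* PLS models are fitted by NIPALS (via mixOmics) on unscaled, centered
  data; the latent-variable search is capped at the numerical rank of the
  calibration matrix so noiseless low-rank data cannot push the algorithm
  past its information content.
* Otsu thresholding errors on constant images; masks that come out
  all-true or all-false are rejected. When the histogram gap between modes
  is empty, any threshold inside the gap is equivalent; agreement with an
  independent implementation is asserted on the induced masks, not the
  cut point.
* Zero-variance bands error in autoscaling (naming the band), yield NA
  with a warning in correlation maps, and are reported as undefined in
  relative-error spectra.
* Ties in classification argmax go to the lowest class index; consensus
  disagreement maps to the reserved label 0.
* Nearest-band lookup accepts a requested wavenumber within half the local
  band spacing and errors beyond it.

## Known limitations

* Mask-based mean-square registration assumes the salient feature is
  common to both modalities; accuracy degrades gracefully (toward ~0.5
  low-resolution pixels on the default phantom) as the modality masks
  diverge, and non-rigid deformation is out of scope entirely.
* The component-contribution metric's normalisation is one reading of an
  ambiguous convention (see above) and its magnitude is not comparable
  across scaling choices.
* Bad-pixel detection targets gross detector faults; subtle
  partially-degraded pixels below 5% of dynamic range pass through.
* High-level fusion inherits its inputs' errors: it can only abstain
  (unknown), never correct.
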