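---
title: "Image-based wheat grain morphometry and MGW prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Image-based wheat grain morphometry and MGW prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainmetry)
```

## The problem

Mean grain weight (MGW, mg) is one of the most frequently measured traits
in wheat breeding and physiology: a sample of several hundred grains is
weighed and the weight divided by the grain count. Weighing is fast, but
repeated, per-plot weighing at scale is not, and classic image-based
substitutes predict weight from the projected grain area, either linearly
or through a power law (`Area^1.32` on a mm² basis, the "Kim index"). Wheat
grain width turns out to be a better linear predictor of MGW than area:
the grain fills late in development mostly across its width, so
width-bearing measures (the fitted-ellipse minor axis `Minor`, the minimum
caliper diameter `MinFeret`) and ratios dominated by width (notably
`Area/Perim.` and its algebraic relatives `Area*Circ.` and `Perim.*Circ.`)
track weight more closely than the two-dimensional area does.

grainmetry re-implements the complete measurement-and-modelling pipeline
behind that observation: segment grains from top-view images taken on a
lit white panel, compute per-grain shape descriptors in the
particle-analysis convention, evaluate a catalogue of empirical predictive
indices, aggregate to per-image means, and fit or apply linear MGW models.
A synthetic scene generator with full ground truth makes every stage
testable without an imaging rig.

## Pipeline and conventions

1. **Resolution enhancement** (`upscale_bicubic()`). Both image dimensions
   are multiplied by an integer factor (reference setting 10) with
   separable bicubic convolution, Catmull-Rom kernel (`a = -0.5`), sampling
   grid aligned at pixel centres. Interpolated intensities are clipped to
   `[0, 255]` rather than wrapped, so overshoot near hard edges cannot
   corrupt thresholding. The mm-per-pixel scale is divided by the factor.
   Enhancement matters because a camera pixel integrates light over its
   footprint: the gray ramp across a grain edge encodes the sub-pixel edge
   position, and interpolating before thresholding recovers it.

2. **Segmentation** (`hsb_threshold()`, `fill_holes()`,
   `label_components()`). The RGB image is converted to HSB and the
   Brightness channel (`max(R, G, B)`) thresholded with the iterative
   intermeans (IsoData) method by default; Otsu and fixed levels are
   available. Foreground is the *dark* side (grains on a lit panel); an
   `invert` flag covers the opposite setup. A histogram with a single
   occupied level yields an empty mask — a uniform image contains no
   darker class. Interior holes (specular highlights) are filled before
   measurement, because a hole corrupts area and solidity while grains are
   physically solid. Connected components use 8-connectivity by default
   and are labelled 1..N in raster-scan order of their first pixel; no
   size or circularity filter is applied, and border-touching regions are
   kept unless `exclude_edges` is set.

3. **Descriptors** (`measure_region()`). All geometry is computed on
   0-based pixel centres.
   * *Area* is the raw pixel count.
   * *Perimeter* comes from the Moore-traced boundary chain. Two
     estimators are provided: the plain chain length (axis step 1,
     diagonal `sqrt(2)`) and the corner-corrected traced estimator (axis
     steps weighted 0.948, diagonal steps 1.340) used by the standard
     particle-analysis tool. The corrected form is the default: the plain
     chain over-estimates a smooth outline by a factor that depends on the
     local tangent direction but *not* on resolution (up to ~8 %), so
     circularity computed from it would not converge under enhancement,
     while the corrected estimator is asymptotically unbiased for smooth
     convex outlines (measured: within 0.5 % on digital disks and
     ellipses).
   * *Major/Minor/Angle* come from an area-preserving moment fit: the
     orientation and axis ratio are those of the second central moments of
     the pixel coordinates, and both axes are then rescaled by a common
     factor so that `pi * (Major/2) * (Minor/2)` equals the pixel-count
     area to floating-point precision. The angle is degrees
     counterclockwise from the +x (column) axis in `[0, 180)`.
   * *Feret/MinFeret* use the convex hull of the boundary pixel centres:
     the maximum pairwise hull-vertex distance, and the exact rotating-
     calipers minimum width (smallest over hull edges of the farthest
     vertex distance from the edge line).
   * *Circularity* is `4*pi*Area/Perim^2` capped at 1; *Solidity* is the
     traced-boundary polygon area over the hull polygon area, capped at 1
     (both polygons pass through pixel centres, so a convex region cannot
     exceed 1 by a discretisation artifact); *AR* is `Major/Minor`;
     *Roundness* is `4*Area/(pi*Major^2)`.
   * *Skew/Kurt* are the standardised third and fourth central moments of
     the grains' grayscale intensities (mean of channels); kurtosis is
     reported as excess kurtosis. Zero-variance regions report `(0, 0)`
     with a degeneracy flag.

4. **Indices** (`compute_catalogue()`). The catalogue contains the twelve
   basic descriptors, twenty-one synthesized products and ratios (for
   example `Area/Perim.`, `Area*Circ.`, `Perim.*Circ.`, the five-factor
   products `A1`/`A2`), and the `Kim index` control. Two algebraic
   identities tie the leading indices to the width-bearing ratio
   `Area/Perim.`: `Area*Circ. = 4*pi*(Area/Perim.)^2` and
   `Perim.*Circ. = 4*pi*(Area/Perim.)`, which the test suite asserts to
   1e-9 on every measured grain. `Area/Perim.^2` equals `Circ./(4*pi)`
   and is retained only for completeness of the preliminary catalogue.
   The Kim index is evaluated only on the mm² basis: a power law is not
   unit-covariant, so a pixel-basis value would depend on the camera
   geometry.

5. **Models** (`aggregate_sample()`, `fit_linear()`, `kfold_cv()`,
   `predict_published()`). The analysis unit is the sample (one image):
   basic descriptors are averaged over grains and the index catalogue is
   evaluated on those means (index of means, not mean of indices — the
   convention under which the reference coefficients were estimated). MGW
   is the sample weight divided by the grain count. Models are ordinary
   least squares `MGW = slope * index + intercept` with R² and
   population-form RMSE (`sqrt(mean(res^2))`). Cross-validation shuffles
   the samples once under a recorded seed and splits them into k
   near-equal folds; held-out RMSE is reported as mean ± sd across folds.
   `published_coefficients()` ships the reference slope/intercept table of
   the twelve retained indices at three measurement scales
   (original-resolution pixels, 10x-enhanced pixels, SI units), and
   `predict_published()` applies it.

## The synthetic scene generator

`generate_scene()` emulates the acquisition conditions the reference
models come from: more than 400 non-touching grains per 960 x 720 px
image at 0.15 mm/px, grain length ~ 6.1 mm with an 8.58 % CV, width ~
2.9 mm with a 12.36 % CV, a length-width correlation of 0.608 (sampled
from a truncated bivariate normal via its Cholesky factor), and a
width-driven per-grain weight law `w = 26.22 * width - 37.43 + N(0, 1.1)`
mg. Driving weight from width (rather than area) gives index-ranking
tests a known right answer; an area-driven law can be configured for null
experiments. Grains are rendered as rotated superellipses with exponent
2.5 — rounder than a rectangle, more angular than an ellipse — and the
exponent is configurable so that descriptor-accuracy fixtures can use
exact ellipses (`squareness = 2`), for which `Minor`, `MinFeret`,
perimeter and circularity all have closed-form truth.

Three generator choices deserve explanation:

* **Placement.** Plain random sequential placement provably jams below
  the target density: 450 grains cover ~43 % of the canvas, and with the
  required 2 px separation the effective exclusion reaches the ~55 %
  jamming limit of random ellipse adsorption. Grains are instead laid out
  the way a vacuum seed counter arrays them: randomly jittered rows
  (shelves), tallest row first, with the horizontal and vertical slack
  redistributed as random gaps and each grain jittered inside its row.
  The orientation half-range is chosen automatically as the widest value
  (up to fully random) for which the layout provably packs; sparse
  canvases get fully random orientations, the dense default narrows to a
  few degrees around horizontal. Placement is deterministic per seed and
  guarantees a pairwise Chebyshev separation of at least 3 px, which the
  suite verifies with a dilation test.

* **Edge rendering.** By default edges are anti-aliased: each boundary
  pixel's intensity is proportional to its sub-pixel coverage (4 x 4
  supersampling), which is what a real sensor integrating over its pixel
  footprint produces. This matters for studying resolution enhancement:
  a hard-binary rendering carries no sub-pixel information, so upscaling
  it cannot (and measurably does not) improve descriptor accuracy,
  whereas with coverage-shaded edges the mean relative error of `Minor`
  drops about fourfold and of `Circ.` about sixfold between factors 1 and
  10. `edge_aa = FALSE` restores hard edges, whose thresholded mask
  equals the ground-truth rasterisation bit for bit — useful for
  segmentation tests.

* **Shape-family bias.** The area-preserving ellipse fit maps a
  superellipse silhouette to an ellipse of equal area, which inflates
  `Minor` by a constant factor (`~3.7 %` at exponent 2.5). This is a
  property of the measurement convention, not an error: applied to real
  grains the same effect is absorbed into the fitted slope and intercept.
  Tests that compare measured width against generator truth therefore use
  either ellipse-family fixtures or `MinFeret` (the unbiased caliper
  width for any convex silhouette).

`generate_dataset()` arranges samples in a balanced 2 x 2 year x
irrigation design with multiplicative mean shifts (defaults: second year
reduces length by 2.480 % and width by 1.566 %; deficit irrigation
reduces length by 1.377 % and width by 5.127 %), deriving per-scene seeds
from one master seed. `simulate_sample_table()` is its statistical
counterpart at the sample level (no rendering): per-sample mean width is
drawn from the group mean plus the within-sample averaging noise
`width_sd / sqrt(n_grains)`, and MGW follows the width law with
sample-level residual noise of 1.1 mg — the scale of scatter the
reference linear models leave unexplained. Parameter-recovery and
cross-validation checks run on 180 such samples.

## Numerical choices and degenerate inputs

* Thresholds are computed on a 256-bin histogram of rounded brightness;
  the IsoData fixed point is iterated to 1e-7. Uniform histograms return
  `level - 0.5` so the mask is empty.
* The bicubic kernel weights sum to 1 algebraically; runs of four equal
  taps are passed through unchanged so constant regions stay bit-exact.
* Single-pixel regions: perimeter 0 with a warning, Feret diameters 0
  with a degeneracy flag. Collinear pixel sets: `minor = 0`, flagged; the
  full descriptor bundle refuses such regions with the region label in
  the error.
* Division by zero in any catalogue ratio names the index and the grain.
* Ellipse angles and Feret angles are reported in `[0, 180)` degrees,
  counterclockwise from the +x axis; ties in the caliper minimum resolve
  to the first hull edge reached.
* `rank_indices()` treats zero-variance indices as `R = 0` with a flag;
  selection requires strictly exceeding both controls.
* Cross-validation uses one stratification-free permutation under a
  recorded seed; fold sizes differ by at most one.

## Verifying the exact calipers against an angle sweep

The test suite compares `MinFeret`/`Feret` against a brute-force caliper
sweep in 0.01° steps. For the maximum diameter the sweep agrees with the
exact pairwise computation to ~1e-9 relative (the width function is
smooth and quadratic around its maximum). For the *minimum* width the
sweep is an upper bound with a V-shaped valley at the flush-edge angle:
its grid minimum sits up to ~5e-3 px (a few 1e-5 relative) above the
exact rotating-calipers value, and refining the step converges toward the
exact value from above. The suite therefore asserts exactness one-sidedly
(calipers ≤ sweep, within the sweep's angular resolution); an equality
assertion at 1e-6 would test the oracle's grid, not the geometry.

## Problem sizes used by the tests

The suite measures full 450-grain scenes at the original resolution, a
12-sample 2 x 2 dataset at enhancement factor 10 (the ranking study),
ellipse fixtures at factors 1 and 10 for the enhancement-effect check,
180 simulated samples for parameter recovery, and 100 random masks / 50
fixture regions for the labelling and caliper oracles. These sizes keep a
complete run in the tens of minutes on one core while leaving every
statistical conclusion comfortably away from its tolerance.

## Known limitations

* Touching grains are not split (no watershed): the acquisition protocol
  this pipeline targets guarantees non-contact, and the generator
  enforces it.
* Absolute perimeter values depend on the corner-correction convention;
  comparisons against tools using the plain chain convention will differ
  by a near-constant factor that cancels inside fitted linear models.
* The mm-per-pixel scale is user-supplied configuration; nothing is
  inferred from image metadata.
* The generator renders flat-shaded (optionally coverage-shaded,
  optionally Gaussian-noised) silhouettes; it does not emulate texture,
  shadows, or lens distortion, so passing its tests demonstrates
  geometric and statistical correctness of the pipeline, not robustness
  to photographic artifacts.
* Reference coefficients apply to the unit system they were estimated
  in; predicting from pixel-basis indices with SI coefficients (or vice
  versa) is refused rather than converted.
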