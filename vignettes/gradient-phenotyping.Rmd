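---
title: "Quantifying plant responses to a red:blue light gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plant responses to a red:blue light gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradphen)
```

## The experimental design this package models

A light-quality gradient experiment places pots on a grid of rows and
columns inside a growth room whose luminary clusters are tuned so that the
red:blue photon-flux ratio varies continuously along the column axis,
while total irradiance (PPFD) stays within a fixed band. Each pot is
identified by room:row:column coordinates, carries a measured red:blue
ratio, and is imaged repeatedly (6 side views over a 180° rotation plus
1 top view) on a twice-weekly cadence across a ~30-day treatment. Species
occupy blocks of contiguous rows (3 rows of 12 pots = 36 pots for most
habits; 4 rows = 48 pots for a flat rosette reference that needs the extra
replication because only its top view is informative), with positions
randomized within each block at treatment start.

The package implements every stage of the analysis of such an experiment
and, because the original raw images are an external archive, a
first-class synthetic generator that emulates the design closely enough to
exercise and validate every downstream stage.

## The gradient statistic

For one species, descriptor $y$ and imaging day, the model is simple
ordinary least squares on the log ratio:

$$y_i = a + b \,\ln r_i + \varepsilon_i,$$

fitted over the $n \ge 3$ pots of that species (`fit_descriptor_gradient()`,
backed by `stats::lm`; an independent normal-equations oracle checks
slope, intercept, $R^2$ and $p$ to $10^{-9}$ in the test suite). The
*effect size* is the signed percent difference between the fitted values
at the extreme observed ratios,

$$E = 100\,\frac{\hat y(r_{\max}) - \hat y(r_{\min})}{\hat y(r_{\min})},$$

computed per species from that species' own observed ratio range (species
occupy different rows, so their pots can see slightly different extremes).

Choices the definition leaves open, and what this package does:

- **Percent baseline.** The denominator is the prediction at the
  *minimal* ratio (blue-most end), so a positive effect reads "larger
  under red-shifted light". `baseline = "max"` and `"mid"` are available;
  the choice only rescales, never re-signs, the effect.
- **Logarithm base.** Natural log internally. Both fitted endpoints are
  base-invariant, hence so are the effect size, $R^2$ and $p$; only the
  slope's unit (per ln-ratio) depends on the base, and it is reported as
  such.
- **$p$-value.** The slope $t$-test, which for simple OLS is numerically
  identical to the Pearson correlation test.
- **Significance categories.** Strict inequalities, `NS`, `p<0.05`,
  `p<0.01`, with configurable thresholds; $p = 0.05$ exactly is `NS`.
- **Multiple testing.** No correction by default, since each cell is
  reported as its own regression; `stats::p.adjust` can be applied to the
  returned `p_value` column by users who need family-wise control.
- **Confidence interval for $E$.** Delta method on $(a, b)$ with the OLS
  covariance matrix and $t_{n-2}$ quantiles. $E$ is a smooth ratio of two
  linear predictors, so the linearization is accurate at the noise levels
  of interest; the acceptance suite measures empirical coverage of
  0.95–0.97 at $n = 36$ and 10 % multiplicative noise for programmed
  effects from −50 % to +50 %.
- **Degenerate inputs.** Constant descriptor values fit as slope 0 with
  $p = 1$ (a flat response is a valid answer); constant ratios raise an
  error (the gradient is unidentifiable); a non-positive baseline
  prediction marks the percent effect undefined rather than returning a
  misleading number.

Repeating the fit at every imaging session gives the effect-size time
course (`effect_time_course()`), with sessions after the configured
treatment end flagged post-treatment.

## Descriptors

`measure_view()` computes, per view, the full measured parameter set:
bounding height/width and pixel-count area (mm via the mm-per-pixel
calibration), perimeter, convex hull area/perimeter, max/min/mean Feret
diameters, moment-equivalent ellipse axes, five shape factors
(roundness = minor/major axis, solidity = area/hull area,
convexity = hull perimeter/perimeter, circularity = $4\pi A/P^2$,
compactness = $\sqrt{4A/\pi}$/major axis), RGB and HSB channel means on
the 0–255 scale, the hue coefficient of variation, integrated density
(pixel count × mean grey), and — from the top-view channel means — GLI,
TGI and the RGB-regression chlorophyll estimate
$440 + 7.266B + 10.873R - 15.545G$. `aggregate_views()` folds 6 side
views and 1 top view into one record: max over side views for
height/width, mean for areas and shape/colour factors, and the volume
proxy $\mathrm{Voxel} = \sqrt{A_{side}^{\max} A_{side}^{\min} A_{top}}$.

Numerical conventions that matter:

- **Perimeter.** A naive count of boundary steps overestimates curved
  boundaries (a digitized disk would get perimeter $\approx 8r$, biasing
  circularity to $\pi^2/16 \approx 0.62$ or, with unweighted chain codes,
  above 1). The package uses the Vossepoel–Smeulders weighted chain-code
  estimate on the 8-connected outer boundary (0.980 per axial step, 1.406
  per diagonal step, −0.091 per corner), under which disk circularity
  converges to 1 from above (1.014 at $r = 100$ px; the limit property is
  tested). Interior holes are not traced; plant silhouettes at this
  resolution are effectively hole-free after component filtering.
- **Convex hull.** Taken over the unit-square *corners* of the foreground
  pixels, not their centres. This guarantees hull area ≥ pixel-count area
  (so solidity ≤ 1 exactly) and makes Feret extents agree with closed
  forms on axis-aligned shapes (a square of side $s$ gets max Feret
  $s\sqrt2$ and mean Feret $s(1+\sqrt2)/2$ exactly). The one residual
  discretization artefact: for convex digitized regions the hull perimeter
  can exceed the chain-code perimeter by ~1 %, so convexity may slightly
  exceed 1 there; it is left as computed rather than clamped.
- **Feret diameters.** Rotating calipers over hull vertices (max = hull
  diameter; min = smallest width over hull-edge directions). Hull-based
  and boundary-based Feret extremes coincide, so the cheaper hull route is
  used; brute-force all-pairs/all-direction oracles confirm both extremes
  to $10^{-6}$ on random masks.
- **Ellipse.** The moment-equivalent ellipse (axes $4\sqrt{\lambda}$ of
  the pixel-coordinate covariance eigenvalues); collinear regions
  degenerate to minor axis 0 and are flagged.
- **Hue statistics.** Arithmetic mean and SD on the 0–255 hue channel —
  deliberately linear, not circular, to match the plain `stdev/avg`
  definition of the coefficient of variation. For red-dominant plants
  whose hues straddle the 0/255 wrap this is discontinuous; such
  foregrounds are flagged (`hue_wrap`) rather than silently corrected.
- **Multi-plant pots.** All components above the minimum area (default
  25 px) are kept and measured as one specimen — bushes sown several
  plants per pot are a single biological unit here.

## Imaging

Side views image a dark plant against a bright, back-lit diffusive
background; top views a bright plant on dark cloth. Segmentation
thresholds inverted brightness (side) or the excess-green index
$2G - R - B$ (top), with Otsu's method selecting the threshold by default
and fixed thresholds available in configuration. White balance applies
per-channel gains equalizing a neutral chart patch's channel means
(idempotent, clipped to [0, 255]); spatial calibration is the patch's
physical size over its pixel size. An empty segmentation is returned
flagged — a legitimate outcome for a failed pot — never raised as an
error, and segmentation is verified invariant (IoU change < 0.01) under
white-balance gains.

## What the synthetic generator emulates — and what it does not

`build_layout()` reproduces the block design (36/48 pots, contiguous rows,
within-block randomization); `build_light_map()` interpolates ln(ratio)
linearly between 5 equally spaced luminary-cluster set-points across the
12 columns, adds per-pot log-normal measurement noise (SD 0.05 on the ln
scale), and draws PPFD uniformly in 100–150 µmol m⁻² s⁻¹. The published
design does not state numeric ratio end-points, so the default gradient
spans 0.1–10 — two decades symmetric about 1, configurable.

`render_scene()` draws a procedural 2.5-D plant — stem plus leaves as
parametric ellipses with 3-D azimuth/elevation, projected into the 6 side
views (30° steps) and the top view — for four habits (rosette,
caulescent, grass, bush with several sub-plants per pot). Growth follows a
saturating curve; a light response multiplies a trait by
$1 + \beta(t)\ln r$, where the slope $\beta(t)$ follows a rise–peak–decay
curve (zero before onset, maximal at the peak day, gamma-like decay;
shape 0 is the constant-slope special case). `slope_for_effect()` inverts
the effect-size definition so a programmed percent effect across the
gradient holds exactly for the noiseless trait; because the log-normal
dimension noise (truncated at 2.5 SD to keep plants inside the frame)
scales both predicted endpoints equally, the programmed effect stays
unbiased under noise. Ground truth (masks, mask-derived dimensions,
colours) is recorded per scene, and `simulate_descriptor_truth()` provides
the same growth/effect/noise model as a direct descriptor table — the
fast path used to study the statistics at scale without rendering.

The default seven-morphotype panel spans the architectural diversity of a
multi-species screen (one rosette reference, caulescent dicots, bushes,
three grasses) with species-specific, partly transient effect dynamics.
Its silhouette shape factors in the fast path are smooth habit-specific
functions of the geometry parameters, and colours are deliberately
similar greens — so dimensions, shape and colour each discriminate only
part of the panel and the full descriptor set is needed for clean
separation, mirroring the real screening situation.

What passing tests on this generator do *not* show: robustness to real
segmentation adversities (soil and moss pixels, specular highlights,
overlapping neighbours, lens distortion), to hue wrap in strongly
non-green tissue, or to biological correlation structure (the noise model
is independent across pots and days). Results on real images depend on
those factors; the generator validates the computational chain, not the
camera.

## Problem sizes and runtime choices

The validation suite runs at the design's native scale where that is
cheap (36-pot blocks, 9 imaging sessions, 200-replicate effect-recovery
simulations, 1000-replicate null calibration) and exercises the full
image pipeline end-to-end on one 36-pot species × 9 sessions × 7 views at
256 × 256 px, 1 mm/px — small frames chosen so a full synthetic
experiment renders and processes in minutes while keeping every descriptor
computable with sub-pixel-relevant accuracy (dimensions within 1 px ×
calibration, areas within 2 % of ground truth, segmentation IoU ≥ 0.95 on
noiseless scenes).

## Multivariate discrimination

`pca_discriminate()` z-scores the selected descriptor columns (PCA on the
correlation structure — the published analysis does not state its scaling,
and correlation scaling is the defensible default when descriptors mix
mm, mm², unitless ratios and colour levels), drops constant features with
a warning and incomplete rows with a message, fixes component signs
(largest-magnitude loading positive), and summarizes separation by the
mean silhouette of species labels on the first two components, overall
and per species pair. A flat rosette species can be excluded from
side-view selections (`exclude_side_for`), mirroring the fact that its
side views are uninformative.

## Known limitations

- The renderer is a silhouette model: no self-occlusion-realistic leaf
  texture, no specular effects, no soil — segmentation difficulty is not
  represented.
- Linear hue statistics are wrong near the hue wrap; flagged, not fixed.
- The effect-size CI is a delta-method approximation; for very small $n$
  or near-zero baselines a bootstrap would be preferable.
- The gradient model is strictly log-linear; thresholds, peaks or troughs
  *within* the ratio range (one motivation for gradient designs) need a
  nonlinear dose-response extension, which is out of scope here.
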