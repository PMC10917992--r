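---
title: "Observer-independent cytoarchitectonic mapping with glimap: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer-independent cytoarchitectonic mapping with glimap: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glimap)
```

## The problem

Cortical areas differ in their laminar architecture: the relative thickness
of layers I–VI and the packing density of cell bodies within each layer.
Classical parcellation by visual inspection of stained sections is
observer-dependent; `glimap` implements the quantitative alternative in
which areal borders are detected as statistically significant changes in the
laminar pattern, and individual delineations are aggregated into
population-level probability maps. The pipeline runs end to end on a
synthetic cortex generator with exact ground truth, which is how every claim
in this vignette is verified.

## The gray level index

The GLI of a square measuring field (default 16 µm side) is the areal
fraction of pixels belonging to stained cell bodies, an estimate of the
cell-body volume fraction. `compute_gli()` defaults to *tile* mode —
non-overlapping fields, with partial edge fields dropped — because tiling
yields an exact conservation law used in testing:

```{r conservation}
mask <- cell_mask(matrix(rbinom(96 * 96, 1, 0.2), 96, 96), resolution = 1)
gli <- compute_gli(mask, field_size = 16)
16^2 * sum(gli$values) == sum(mask$pixels[1:96, 1:96])
```

A sliding mode (`stride =` pixels) produces smoother images for profile
extraction. Segmentation of grayscale images into cell masks is an explicit
user decision (`binarize()` with a stated threshold and foreground
convention); no threshold is ever guessed silently.

## Laplace traverses and laminar profiles

Profiles must be sampled perpendicular to the cortical layers. `glimap`
models the cortical band between the outer (layer I/II) and inner (layer
VI/white matter) contours as a capacitor: `solve_laplace()` computes the
harmonic function with value 0 on the outer contour and 1 on the inner one,
and `trace_traverses()` integrates gradient streamlines seeded at
equidistant arc-length positions on the outer contour. Streamlines of a
harmonic field cannot cross, so traverses partition the band.

Numerical choices:

* The field is discretized on a regular grid (spacing in µm is a user
  parameter) with a Shortley–Weller scheme: where a grid link crosses a
  contour, the finite-difference arm is shortened to the actual crossing
  distance (floored at 0.05 of a step for conditioning). This keeps the
  boundary error second-order; on a concentric annulus sector sampled at
  roughly 150 × 280 nodes the field matches the closed form
  $\ln(r/r_{out})/\ln(r_{in}/r_{out})$ to better than $10^{-2}$
  (measured: about $2\times10^{-3}$), the scale at which the acceptance
  suite checks it.
* The two lateral edges of an open band get reflecting (zero-flux)
  conditions, which avoids edge distortion of the outermost traverses. At
  band corners, where a contour meets a lateral edge, the Dirichlet value
  wins.
* The linear system is solved directly (sparse LU via Matrix), so
  "convergence" reduces to a residual check reported on the result object.
* Streamlines use RK2 steps of a quarter grid spacing, bilinear
  interpolation of the gradient, and join the inner contour by projection
  once the field exceeds 0.985; a streamline that leaves the band laterally
  is flagged and excluded rather than repaired.
* Coordinates are 0-based pixel indices with pixel centers at integer
  multiples of the resolution; arc length is in µm.

`extract_profile()` samples a GLI image by bilinear interpolation at equal
arc-length steps along a traverse, and `normalize_profile()` resamples
linearly onto `D = 101` equidistant points spanning 0–100 % cortical depth.
101 points give an integer-percent grid, which simplifies reporting; the
resampling is idempotent.

## Feature vectors and border detection

Each profile is reduced to a 10-dimensional descriptor: mean GLI, cortical
centroid depth (GLI-weighted mean depth), standard deviation, skewness and
kurtosis, plus the same five statistics of the absolute first-difference
sequence ("first derivative"). Two moment conventions exist in the
literature's wake: moments of the profile's *values*, or moments of the
*depth distribution* obtained by treating GLI as a mass density over depth.
`profile_features()` defaults to the values convention — under which a
constant profile has zero spread, the behavior the validation suite pins
down — and exposes `moments = "mass"` as a switch; the centroid is the
mass-weighted depth under either convention. With zero derivative mass
(a constant profile) the derivative centroid falls back to uniform weights
(mid-depth).

Border detection compares the `b` profiles left and right of each position
(the position index `i` names the boundary between profiles `i` and
`i + 1`):

* $D^2 = (\bar{x}_a - \bar{x}_b)^\top C^{-1} (\bar{x}_a - \bar{x}_b)$ with
  the pooled within-block covariance $C$;
* $T^2 = \frac{n_a n_b}{n_a + n_b} D^2$, converted exactly to
  $F = T^2 \frac{n_a + n_b - p - 1}{(n_a + n_b - 2)p}$ with
  $(p,\; n_a + n_b - p - 1)$ degrees of freedom;
* Bonferroni correction over the number of positions tested per section and
  block size, at familywise level $\alpha = 0.001$.

With `b = 12` and `p = 10` the pooled covariance rests on only 24
observations, so whenever $2b \le 3p$ it is shrunk toward its diagonal with
the analytic (Ledoit–Wolf-style) intensity of Schäfer & Strimmer (2005);
this keeps the matrix well-conditioned at the small end of the default
block-size sweep 12–30. Because shrinkage perturbs the exact $T^2$
distribution, the null-calibration check (uniform p-values under a
multivariate normal null, KS test) is run in a regime where shrinkage is
off; type-I control of the full shrunk pipeline is verified separately by
simulation.

Candidate borders are strict local maxima of $D^2$ within ±b/2 positions,
restricted to positions whose window is complete (an end-adjacent maximum is
not interior), and significant after Bonferroni. `accept_borders()` then
applies the consistency rule: candidates are clustered by position (single
linkage, gaps above `position_tolerance = 3` indices split clusters), and a
cluster is accepted only if at least `min_sections = 3` *adjacent* analyzed
sections each support it with at least two distinct block sizes. The
consensus position is the median candidate position; the summary p-value is
conservatively the largest corrected p among the supporting candidates.

## The synthetic cortex generator

The generator is first-class, tested code; its defaults define the study
conditions for every simulation-based guarantee.

* **Laminar model.** Six layers with thickness fractions
  (0.10, 0.08, 0.30, 0.10, 0.20, 0.22) — a thin II and IV, broad III, V and
  VI, i.e. granular isocortex — and per-layer target GLI levels
  (0.10, 0.24, 0.16, 0.27, 0.17, 0.20), in the range reported for human
  isocortex. Somata are disks (default radius 4 µm) placed by a Poisson
  process, so layer coverage has the Boolean-model closed form
  $1 - e^{-\lambda \pi r^2}$, which `render_ribbon()` is tested against;
  `intensity_for_gli()` inverts it. Overlap is allowed deliberately — it is
  what makes the closed form exact.
* **Geometries.** A flat rectangle, and an annulus sector for which the
  Laplace field has the radial closed form used as a geometric oracle.
* **Noise.** In the fast path (`sample_profiles()`), profiles are the
  noiseless laminar curve plus i.i.d. Gaussian noise (default sd 0.05)
  clipped to [0, 1]; injecting noise at the profile level lets the
  statistical tests control the effect size exactly. In the image path the
  noise arises from the point process itself. A planted border is a change
  of laminar model at a known arc-length position, e.g. a +50 % layer-IV
  density step.
* **Populations.** `make_label_volumes()` displaces a base label volume
  through a smooth random deformation (white noise, separable box-filter
  smoothing, amplitude `jitter_sd` voxels, nearest-neighbor pull-back), so
  per-voxel subject counts stay exact integers.

What the generator does *not* emulate: neuron morphology, glial/endothelial
nuclei, staining artifacts, tangential cutting, 3-D section stacks, or real
registration error. Passing tests therefore demonstrate the correctness and
calibration of the computational pipeline under its stated model, not
robustness to histological artifacts — the step the original workflow
covers by visual quality control.

Simulation sizes were chosen to give stable estimates at modest cost: the
type-I check runs the full pipeline (block sizes 12–30, three sections of 70
profiles) on 200 seeded homogeneous ribbons; border recovery uses 100 seeded
two-area ribbons (three sections of 40 + 40 profiles, +50 % layer-IV
contrast, noise sd 0.05) and requires the accepted border within ±3 profile
indices of ground truth; on these conditions the measured familywise false
acceptance is 0/200 and recovery is 100/100.

## Areal statistics

`mean_area_profile()` averages profiles pointwise and reports the scalar
mean GLI. `cluster_areas()` performs Ward agglomeration on Euclidean
distances between mean areal profiles — a high distance meaning a large
cytoarchitectonic difference — with merge heights reported as
error-sum-of-squares increments, the quantity Ward's criterion minimizes
(`stats::hclust` ward.D2 heights are $\sqrt{2\,\Delta ESS}$; the package
converts and the tests verify against an exhaustive ESS oracle). Clustering
operates on mean profiles by default; feature-vector matrices can be passed
just as well, since the function accepts any numeric matrix.
`discriminant_projection()` computes canonical axes maximizing the
between/within scatter ratio, with a small ridge on the within-class
scatter only when it is numerically singular, and axis signs fixed by
making each axis's largest loading positive.

Volumetry follows the section-based formula
$V = s \cdot T \cdot x \cdot y \cdot \sum_i N_i \cdot F$ (sampling interval
`s` in sections, thickness `T` and pixel sizes `x`, `y` in mm, labeled pixel
counts `N_i`, shrinkage factor `F`). The shrinkage factor is an input, not
estimated; integer pixel counts are summed exactly (no floating-point loss
below $2^{53}$), and `normalize_volume()` divides by total brain volume.

## Population maps

`probability_map()` counts, per voxel, the fraction of subjects assigning
the voxel to an area; with `n` subjects every value is an exact multiple of
$1/n$ because counting is integer. `maximum_probability_map()` assigns each
voxel to the area of highest probability (background where none has
support). Exact ties — common at area boundaries with 10 subjects — are
broken deterministically: higher mean probability in the 26-voxel
neighborhood first, then the lower area index. No minimum-probability
threshold is applied by default; a `threshold` argument exists for display
parity with atlas color scales that start at 10 %. `center_of_gravity()`
maps the probability-weighted mean voxel index through the stored affine
(0-based voxel indices; background label 0 is reserved). Volumes are
assumed pre-aligned on a shared grid; registration to standard templates is
out of scope.

## Known limitations

* The Laplace discretization floors shortened arms at 0.05 of a grid step,
  which bounds the field error near contours at roughly
  $0.05\,h \cdot |\nabla u|$; halve the grid spacing where that matters.
* Traverse seeds are equidistant on the outer contour only; no
  equivolumetric depth model is provided.
* The acceptance rule treats "adjacent sections" as consecutive analyzed
  sections, whatever their physical spacing.
* Derivative features use the absolute first difference; signed-derivative
  variants would require only a small extension but are not implemented.
* The discriminant projection is descriptive (visualization); it performs
  no classification or cross-validation.
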