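---
title: "Continuous diaphyseal morphometry with cortmap: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous diaphyseal morphometry with cortmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortmap)
```

## The measurement model

A long bone diaphysis is treated as a hollow beam.  From a segmented,
landmark-positioned voxel volume, `cortmap` extracts 17 cross sections at
25% to 65% of mechanical length in 2.5% steps — the region of the shaft
where cortical bone dominates and trabecular bone does not bias the
measurements.  Within each section, 360 rays from the area centroid of the
cortical pixels (one-degree increments, counter-clockwise, ray 0 along the
reference/medial direction) give paired periosteal and endosteal radii;
their difference is the radial cortical bone thickness
$t(\varphi) = R_p(\varphi) - R_e(\varphi)$.

Bending stiffness is summarized by second moments of area about 360
neutral axes through the centroid,
$$ I(\theta) = I_{xx}\cos^2\theta + I_{yy}\sin^2\theta
   - 2 I_{xy}\sin\theta\cos\theta, $$
where $I_{xx} = \sum y^2 a^2 + n a^4/12$ (and analogously $I_{yy}$,
$I_{xy}$) are raw moments from pixel summation with pixel size $a$ and the
per-pixel self moment $a^4/12$ included, so coarse grids remain consistent
with the continuum formula.  The axis for ray 0 is parallel to the
reference (medio-lateral) direction; $I(\theta) = I(\theta + 180^\circ)$
by construction, a redundancy retained because it makes the resulting maps
read naturally around the full circumference.

Thickness is standardized by mechanical length ($sCBT = t/L$,
dimensionless); SMA by the product of body mass and length
($sSMA = I/(M\,L)$, mm^3^/kg).  Masses enter as group- and sex-specific
means, either measured directly or estimated from femoral head diameter
through user-supplied sex-specific regression coefficients.

Each individual then yields one 17 × 360 morphometric map per property
(rows proximal to distal, columns degrees from the reference direction).
Groups are summarized by pixelwise mean (consensus) maps and pixelwise
coefficient-of-variation maps ($sd/mean$, $n-1$ denominator — the samples
are small, so the unbiased-variance convention matters).

## Positioning protocol

Two landmarks at the centers of the proximal and distal articular surfaces
define the mechanical axis; the volume is rigidly rotated so this axis is
parallel to z (proximal at lower z), rolled about z until the roll
reference direction parallels +y, and right-sided elements are mirrored
across x into left form so antimeres are comparable.  Rotation and
translation are composed and applied in a single nearest-neighbour
reslicing pass: one interpolation, and binary masks never acquire
fractional labels.  Linear interpolation with re-thresholding is used when
a grayscale volume is supplied.

## Penalized discriminant analysis

With $p = 17 \times 360 = 6120$ correlated pixels and a few dozen
individuals, ordinary LDA is singular.  `fit_pda()` implements penalized
optimal scoring: class indicators are regressed on the centered design
under a quadratic roughness penalty $\lambda\,\Omega$, optimal scores are
extracted by an eigen decomposition, and the resulting discriminants are
those of an LDA whose within-class covariance is regularized to
$\Sigma_W + (\lambda/n)\,\Omega$.  $\Omega$ is the graph Laplacian of the
map grid, with wrap-around adjacency in the degree dimension (the map is a
cylinder: column 0 neighbours column 359) and none in the section
dimension.  Its null space is the constant map, so a uniform offset is
never penalized.  A tiny ridge $\varepsilon = 10^{-8}\,\mathrm{tr}(X_c^\top
X_c)/p$ keeps the system invertible; if an extreme $\lambda$ still renders
the metric numerically semidefinite, the ridge is bumped by the smallest
power of ten that restores definiteness.

Model complexity is measured by effective degrees of freedom, the trace of
the penalized smoother, computed as $\sum_i a_i/(1+a_i)$ over eigenvalues
$a_i$ of the penalized-metric Gram matrix.  It is continuous, monotone
non-increasing in $\lambda$, and tends to 1 (the Laplacian null-space
dimension) as $\lambda \to \infty$.

$\lambda$ is chosen by repeated stratified cross-validation: each fold
holds out one member per group (12 folds × 3 for the canonical 36-row
training set), repeated 100 times; across the repeat means an approximate
95% prediction band (mean ± t-quantile × sd of repeat means) is formed.
All $\lambda$ whose mean error does not exceed the minimum observed upper
band limit are admissible, and the admissible $\lambda$ with the lowest
degrees of freedom wins.  The comparison is tie-inclusive (≤): with a
perfectly separable cohort every repeat can give identical error, the band
collapses onto the mean, and a strict inequality would leave nothing
admissible — whereas the intended behaviour (and the one implemented) is
that the smoothest perfect classifier is selected.  Ties in nearest-
centroid classification are broken deterministically by group order.

Discriminant variates are rescaled to unit pooled within-class standard
deviation before nearest-centroid classification, making distances in
discriminant space Mahalanobis-like; the rescaling is a per-axis scalar
and does not change loading directions.

## The phantom generator

Phantoms are analytic hollow tubes: an outer radius function and a radial
wall-thickness function of (angle, fractional length), voxelized by a
center-of-voxel membership test with no anti-aliasing — matching binary
segmented renderings.  Ground truth is computed from the analytic
boundaries *before* voxelization: the radial thickness map directly from
the wall function, and SMA by dense quadrature (14 400 angular samples per
section) of the boundary curves, an oracle entirely independent of the
pixel-summation code path it validates.

The default cohort emulates a three-species comparative design of 43
adults (14 + 14 + 15): two thick-walled groups of similar standardized
thickness, one of which carries a plantar-proximal local thickening
(centered at 270°, 32% length) whose amplitude varies strongly between
individuals, and a thin-walled group with a dorsoplantarly elongated outer
contour.  Between-individual variation is a multiplicative lognormal
jitter on wall thickness (sdlog 0.08) and overall size (sdlog 0.05),
additive angular phase jitter (sd 4°), lognormal jitter of the thickening
amplitude (sdlog 0.5), smooth angular perturbation of the outer surface
(sd 0.12 mm), mechanical lengths near 60 mm, and a mixture of left and
right elements to exercise mirroring.  These magnitudes are calibration
choices — chosen once as plausible for within-species shape variance,
which no quantitative source pins down — not established facts, and the
cohort does not emulate trabecular bone, metaphyses, diaphyseal curvature,
or scanner physics.  Passing tests on phantoms therefore demonstrate that
the measurement and discrimination machinery recovers known structure
through voxelization, repositioning and resampling; they do not
demonstrate segmentation robustness on real CT data.

Phantom volumes are generated at 0.3 mm voxels for cohort-scale runs and
0.1 mm voxels for the high-resolution recovery checks; both sizes satisfy
the generator's sampling-adequacy invariant (voxel ≤ half the minimum wall
thickness).

## Numerical choices

* **Section plane**: the single resliced z level nearest the exact
  fraction; no slab averaging (per-level images are the unit of analysis).
* **Resampling**: sections are standardized to 0.1 mm pixels by nearest
  neighbour, so masks stay binary and the angular reference is preserved.
* **Hole filling**: background components are labelled; the border-
  touching component is the exterior, the largest enclosed component is
  the medullary canal (preserved), and remaining enclosed pores (e.g.
  nutrient-artery passages) are filled.  Idempotent.
* **Boundary smoothing**: boundary-layer pixels are kept iff the
  bivariate-normal-kernel-weighted occupancy is ≥ 0.5 (a symmetric
  include/exclude rule); interior pixels are never touched.  The kernel
  bandwidth is 0.2 mm (2 pixels) by default and exposed in the
  configuration, since no authoritative value exists.
* **Ray-boundary intersection**: marching at 0.25-pixel steps along each
  ray with linear subpixel refinement of the 0.5-occupancy crossing of the
  bilinearly interpolated mask; outermost crossing → periosteal, first
  entry into bone → endosteal, intermediate crossings ignored; rays
  starting inside cortex get endosteal radius 0.
* **Connected components**: the largest foreground component is kept, with
  a warning when stray specks are discarded.
* **Display**: color maps are upsampled for display only, with bilinear
  interpolation on the angle-wrapped (torus-in-angle) grid to avoid a seam
  at 0°/360°; the 17 × 360 data matrix is never altered.  Degenerate
  anchors (min = max) render a uniform mid-color with a warning.

## Open design points, resolved

* **Centroid definition**: cortex-only (bone pixels), not the filled
  contour — the standard cross-sectional-geometry convention; an eccentric
  medullary canal therefore shifts the centroid as it should.
* **Mirror plane**: reflection of x after alignment (the medio-lateral
  axis under the positioning conventions).
* **CV hot-spot localization**: a planted variability band is an extended
  region; its position is estimated by the CV-excess-weighted circular
  mean angle rather than the argmax column, because amplitude-plus-phase
  jitter makes CV profiles flank-heavy and the argmax a biased estimator
  of band position.
* **Loading-region delineation**: "the region a discriminant highlights"
  is operationalized as its half-maximum (FWHM) region after orienting the
  axis so the planted-thicker group scores positively.

## Known limitations

* Nearest-neighbour reslicing of coarsely voxelized volumes contributes
  boundary errors up to about one voxel after large rotations; recovery
  tolerances at 0.3 mm voxels are correspondingly looser than at 0.1 mm.
* The df-parsimony rule for selecting $\lambda$ (lowest admissible degrees
  of freedom) intentionally favors smooth discriminants.  On the default
  cohort this smoothing spreads the second discriminant's half-maximum
  region beyond the planted thickening, so region-overlap scores of the
  loading map against the planted Gaussian sit below what the consensus-
  map difference itself achieves; classification is unaffected (zero
  test-set errors).  Sharper loading localization would require either a
  prediction-optimal (not parsimony-optimal) $\lambda$ or a sparsity
  penalty, both out of scope.
* CV maps are a crude instrument when group means differ: lower-mean
  groups show inflated CVs purely through the denominator.
* Diaphyseal curvature is not modelled; sections are taken perpendicular
  to the straight landmark axis.
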