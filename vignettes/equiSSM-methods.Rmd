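---
title: "Shape modeling of equine long bones: methods and design notes"
author: "equiSSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape modeling of equine long bones: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the statistical
shape model it builds, the biometric constructions it measures, the
synthetic data it validates against, and the places where the design was
genuinely open and a choice had to be made.

## The model

A statistical shape model (SSM) represents a population of corresponded
surfaces by a mean and orthogonal modes of variation. Given $K$ bones,
each reduced to the same $N$ template vertices, every bone is a vector
$x_i \in \mathbb{R}^{3N}$ and the model is

$$x \approx \bar{x} + \sum_{k=1}^{m} s_k \sqrt{\lambda_k}\, \phi_k,$$

with $\bar{x}$ the vertex-wise mean after generalized Procrustes
alignment, $\phi_k$ orthonormal eigenvectors of the sample covariance
(divisor $n-1$, computed on the $K \times K$ Gram matrix since
$3N \gg K$), $\lambda_k$ the eigenvalues sorted non-increasing, and $s_k$
a score in standard-deviation units. At most $n-1$ modes exist;
numerically null directions (eigenvalues below $10^{-8}$ of the leading
one) are dropped, and a final QR pass scrubs round-off from the trailing
modes. Compactness is the cumulative eigenvalue fraction, and the
mode-count rule selects the smallest $m$ reaching 95%.

The pipeline that produces the corresponded vectors is:

1. **Preprocess** (optional for clean meshes): Taubin smoothing, closure
   of sub-resolution gaps, and isotropic remeshing toward a uniform
   target edge length.
2. **Mirror** right-side bones across $x = 0$ into left-limb convention;
   the plane is immaterial because later stages remove pose.
3. **Similarity ICP**: each sample is aligned to a template by rotation,
   translation and uniform scale. Every iteration matches a random 75%
   subset of the sample vertices to nearest template vertices and solves
   the closed-form (Umeyama) similarity; a candidate update is accepted
   only if it lowers the RMS distance of a fixed evaluation subset to the
   template *surface*, so the reported objective trace is non-increasing.
   Initialization tries the four proper principal-axis alignments plus
   the centroid/scale match and keeps the best.
4. **Warp**: a coarse-to-fine Gaussian radial-basis deformation of the
   template, driven by mutually nearest vertex pairs (kernel widths 0.4,
   0.15 and 0.06 of the template bounding-box diagonal; ridge
   regularization $10^{-4} n$), followed by exact closest-point projection
   onto the sample surface. The face list never changes; inverted-normal
   fractions above 1% abort the registration.
5. **Template refinement**: the Procrustes/PCA mean of pass one becomes
   the template of pass two, removing the bias of the arbitrary initial
   template (which defaults to the sample of median vertex count).
6. **Scale handling**: the ICP scale is *inverted* after warping, so each
   corresponded bone re-enters Procrustes at its native size, and
   Procrustes removes pose only (`removeScale = FALSE`). This is the only
   configuration under which "scaling" can emerge as mode 1, which is the
   salient biological signal in long-bone populations; size-free analysis
   remains available via `removeScale = TRUE`.

Generalization is evaluated by leave-one-out: refit the model on $n-1$
corresponded bones, pose-align the left-out shape to the fold mean,
project onto the first $j$ modes and score the reconstruction. Two error
curves are reported: the vertex-space RMS error, which is exactly
non-increasing in $j$ because the projections are nested least squares,
and the symmetric mean surface distance to the left-out original (the
part-comparison metric), which follows the same trend but is not
guaranteed monotone at the $10^{-9}$ level. Correspondence is established
once across all samples and only the Procrustes/PCA stage is refit per
fold; re-registering every fold from scratch would multiply runtime by
$n$ without changing what the analysis exercises on synthetic data.

## Biometric constructions

All measurements are built from named vertex regions, never from the
scanner frame, which makes them rigid-motion invariant by construction.
The anatomical frame uses the diaphyseal axis (proximal→distal), the
transcondylar or plateau medial→lateral direction, and their cross
product; coronal, sagittal and transverse "views" are projections onto
the frame planes.

Key choices:

* **Axes.** Tubular axes (diaphysis, femoral neck) are estimated from
  *surface normals*: every face normal of a tube is perpendicular to its
  axis, so the axis is the least-variance eigenvector of the
  area-weighted normal scatter. The dominant-spread point fit
  (`fitAxis`) is exported and is exact for symmetric ring samplings, but
  it is biased by uneven vertex densities on remeshed or corresponded
  patches, where the normal-based estimator is not; the measurement
  functions therefore use `fitAxisNormals`.
* **Spheres.** Algebraic (Pratt-style) initialization refined by
  geometric Gauss–Newton on orthogonal distances; coplanar inputs are
  rejected.
* **Angles.** `projectedAngle` returns the unsigned angle in
  $[0,180]°$, optionally after projecting both vectors onto a view
  plane; `lineAngle` folds to $[0,90]°$ for undirected lines. The neck
  angle uses the full angle between the oriented neck axis and the
  distally directed anatomical axis (≈157°); FMA, version, tubercle, CTP
  and CTS use the folded form, matching how these magnitudes are read
  clinically. Valgus/varus is $90° - \mathrm{CTP}$, positive = valgus.
* **Curvature border.** The medial tibial condyle is separated from the
  intercondylar eminence by thresholding discrete Gaussian curvature
  (angle deficit over the Meyer mixed Voronoi area) at mean + 1 SD over
  the region, mesh-boundary vertices excluded; the dividing line runs
  through the selected border perpendicular to the caudal→cranial
  direction. An optional Laplacian pass can smooth the curvature field
  first (off by default). If no vertex exceeds the threshold the medial
  width falls back to the full region extent and is flagged.
* **Femoral medial condylar width** is measured from the most medial
  condyle point to the intercondylar midline (the plane through the
  fitted condylar center normal to ML). Both ends are smooth features of
  fitted primitives, so the measurement is stable under resampling,
  unlike a construction that chases individual crease vertices.
* **Mode ranges.** `modeRangeSummary` measures a biometric on the seven
  canonical instances (−3…+3 SD) of one mode;
  `percentIncrease = 100\,(v_{+3} - v_{-3})/v_{-3}` (reported rounded to
  the nearest integer percent) and `rangeWidth = v_{+3} - v_{-3}`. The
  same arithmetic applied to published mode tables reproduces their
  reported percent changes; `modeRangeStats` exposes it for externally
  supplied rows.

The mode–biometric correlation experiment draws each varied mode's score
independently from Uniform(−3, 3) (a Gaussian alternative is available
and the choice is recorded in the report), generates the instances,
measures all biometrics and correlates each against each mode score with
Pearson's $R$ and the two-sided $t$ p-value. No multiplicity correction
is applied; raw p-values are reported against the 0.05 convention. The
medial vs lateral caudal-slope comparison is a paired $t$ on the per-
instance difference, reported as mean ± SD.

## The synthetic bone generator

No public mesh population of equine femora/tibiae exists, so the package
ships a parametric generator whose outputs make every measurement
construction analytically checkable:

* The **femur** is a closed tube: a distal cap formed by rays onto the
  union of two condylar spheres (radius 36 mm, bicondylar width
  106.7 mm at scale 1), a flared metaphysis, a cylindrical shaft, a bend
  into a cylindrical neck (angle 157.3°, version 43.5°) ending in the
  femoral head sphere (radius 36.1 mm) placed on the 6.7° FMA cone, with
  trochlear-tubercle and greater-trochanter sphere bumps grafted onto
  the wall. Landmark vertices (sphere poles, condylar extremes) are
  snapped exactly onto their analytic positions, and regions are labeled
  from the construction, so `measureFemur` recovers every generative
  parameter to machine precision on the generated mesh.
* The **tibia** is a tube whose top cap is an elliptical plateau split
  into planar medial and lateral facets with independent caudal slopes
  (9.6° and 17.6° at reference), a coronal tilt (CTP 88.9°), and a
  raised concentric mesa whose cliff edge exercises the curvature-border
  rule non-trivially: the cliff ring carries concentrated positive
  curvature, its foot negative, and the facets none, so the mean + 1 SD
  rule isolates exactly the edge.
* **Populations** emulate a scale-dominant bone population: uniform
  scale is lognormal (sdlog 0.08, roughly ±15% across a small
  population) and angles vary independently and Gaussianly around the
  reference values, with the lateral slope equal to the medial plus
  N(6°, 1°). Draws are clamped into the generator's validity bounds.
  Sample sizes of 15 femora and 14 tibiae define the study conditions
  for the acceptance analyses.

The bones are deliberately stylized — smooth analytic primitives with
exact labels — not anatomically faithful surfaces. Passing tests on them
demonstrates that the pipeline's algorithms are correct and
self-consistent (registration fidelity, mode recovery, measurement
accuracy), not that segmentation noise, cartilage remnants, or
pathology-driven shape variation in real CT data would be handled with
the same accuracy. Two known gaps: synthetic surfaces are noise-free
(smoothing is exercised on separately noised fixtures), and the
correspondence problem is easier than on real bones because all samples
come from one construction.

On the synthetic study populations the leading mode explains a larger
variance fraction (≈98–99%) than is typical of real populations
(80–90%), because the generator's non-scale variation is low-dimensional;
the qualitative structure — scaling dominates mode 1, all size
biometrics correlate strongly with it, the lateral slope exceeds the
medial — is the property the acceptance analyses assert.

## Numerical choices and degenerate inputs

* Units are millimetres throughout; meshes whose bounding box is under
  50 mm trigger a warning, not an error.
* ICP accepts an update only on strict improvement and stops after three
  non-improvements (improvements below $10^{-4}$ relative count as
  non-improvements); convergence failure is a provenance flag, not an
  error.
* Procrustes converges when the mean shape changes by less than
  $10^{-7}$ mm; mode signs are fixed so that increasing score increases
  centroid size (ties broken by the largest-magnitude component).
* `extremeVertex` breaks ties deterministically by lowest index; a zero
  direction is an error.
* Sphere fits reject fewer than 4 points or coplanar input; axis fits
  flag near-isotropic clouds (spread ratio < 2) rather than failing.
* The degenerate paired-$t$ case (constant nonzero differences) is
  reported as infinite $t$ with $p = 0$ and a flag; identical series
  give $t = 0$, $p = 1$.
* Samples that fail registration (audit distance above `epsCorr`, 1 mm
  by default, or folded faces above 1%) are rejected and reported; the
  pipeline continues while at least 3 samples survive.
* Region labels are defined once on the template and shared by all
  corresponded samples and model instances — the package's reproducible
  substitute for the manual surface selections of interactive tools.
  `transferRegionLabels` moves labels to remeshed surfaces via the
  supporting face (all three corners must carry the region), which keeps
  sphere and axis fits uncontaminated; regions used only through a
  directional extreme can opt into the nearest-vertex rule.

## Problem sizes

The test suite and the acceptance script run the full pipeline at a mesh
resolution of 8 mm (about 1,400 vertices per femur), with 15-femur and
14-tibia populations, 100-instance correlation experiments, and a
30-bone parameter-recovery set; the remeshing invariance check uses a
4 mm source mesh remeshed at 4.5 mm. These sizes were chosen so the whole
analysis reruns comfortably on a single CPU while leaving every algorithm
with realistic work to do; all of them scale up by changing
`meshResolution` and the population sizes.

## Limitations

* The warp is proximity-driven, so on rotationally symmetric surfaces
  (the femoral head) corresponded points can slide tangentially; sphere
  fits and all shipped biometrics are insensitive to this, but
  point-level correspondence on such regions should not be
  over-interpreted.
* Specificity (plausibility of random instances) is not evaluated; the
  evaluation suite covers compactness and generalization.
* Partial or fragmented bones are out of scope for registration.
* The CLI surface is the package's functions plus the thin scripts under
  `scripts/`; there is no standalone multi-command executable.
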