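# equiSSM

Statistical shape modeling (SSM) and biometrics of equine long bones.

Equine stifle disorders are hard to study because the femur and tibia are
too large to image routinely in vivo, so population-level descriptions of
their shape variation are scarce. `equiSSM` implements the standard
point-correspondence SSM workflow for triangle-mesh bone populations and
the full stifle biometric suite, end to end in R:

* **Mesh handling** — STL/PLY/OBJ I/O, welding, manifold validation,
  mirroring of right limbs into left-limb convention, Taubin smoothing,
  small-gap repair and uniform isotropic remeshing
  (`loadMesh`, `mirrorToLeft`, `smoothMesh`, `remeshUniform`).
* **Correspondence** — similarity ICP alignment of every sample to a
  template (random 75% vertex subsets, up to 50 iterations) followed by a
  coarse-to-fine Gaussian radial-basis warp and exact closest-point
  projection; the PCA mean of the first pass becomes the template of the
  second pass (`alignSimilarity`, `warpCorrespondence`,
  `buildCorrespondenceSet`).
* **Shape model** — generalized Procrustes alignment (pose only by
  default, so bone size survives into the model), PCA on the sample Gram
  matrix with at most *n − 1* modes, instance generation
  `mean + sum(s_k * sqrt(lambda_k) * phi_k)`, compactness and the 95%
  mode-count rule, and leave-one-out generalization
  (`generalizedProcrustes`, `fitShapeModel`, `instanceMesh`,
  `cumulativeVariance`, `selectModes`, `leaveOneOut`).
* **Biometrics** — femur: length, bicondylar width, medial condylar
  width/depth, best-fit medial-condyle and femoral-head sphere radii,
  FMA, neck, trochlear-tubercle and version angles; tibia: length,
  bicondylar width, medial condylar width (via the mean + 1 SD Gaussian
  curvature border of the intercondylar eminence), medial condylar depth,
  CTP angle and the medial/lateral caudal tibial slopes
  (`measureFemur`, `measureTibia`, `modeRangeSummary`, `valgusVarus`).
* **Statistics** — Pearson correlations of each biometric against each
  mode score over randomly generated instances, and the paired t
  comparison of medial vs lateral caudal slope (`correlationExperiment`,
  `pearsonCor`, `pairedT`).
* **Synthetic bones** — a parametric generator of stylized femur-like and
  tibia-like closed meshes with exact region labels and analytically known
  biometrics (`SyntheticBoneParams`, `makeBone`, `samplePopulation`), so
  every stage of the pipeline is testable without CT data.

The central objects are S4 classes with validity checks and accessors:
`TriangleMesh`, `CorrespondenceSet`, `ShapeModel`, `BiometricSet`,
`SimilarityTransform`, `AnatomicalFrame`.

## Worked example

Build a shape model from a small synthetic femur population and inspect
its leading mode:

```r
library(equiSSM)

pop    <- samplePopulation(8, "femur", spec = list(meshResolution = 8),
                           seed = 42)
meshes <- lapply(pop, `[[`, "mesh")
meshes[[1]]
#> TriangleMesh: 1382 vertices, 2760 faces
#>   bounding box (mm): 149.2 x 85.6 x 478.9
#>   regions: medial_condyle, lateral_condyle, femoral_head, femoral_neck, ...

set.seed(42)
corr  <- buildCorrespondenceSet(meshes, templateIterations = 2)
model <- fitShapeModel(generalizedProcrustes(corr))
model
#> ShapeModel: 7 modes from 8 samples, 1382 vertices
#>   mode-1 variance fraction: 0.971

round(cumulativeVariance(model), 3)
#> [1] 0.971 0.989 0.997 0.999 1.000 1.000 1.000
selectModes(model)          # modes needed for 95% of the variance
#> [1] 1

modeRangeSummary(model, 1, "length", measureFemur)
#> ModeRangeSummary (length, mode 1)
#>   -3SD   -2SD   -1SD    0SD   +1SD   +2SD   +3SD
#> 107.54 120.00 132.46 144.93 157.40 169.88 182.35
#>   increase -3SD -> +3SD: 69.6% (~70%)
#>   range width: 74.81 mm
```

The first mode is scaling: it explains 97% of the variance in this
population and the femur length of the ±3 SD instances grows monotonely
across the mode range. Correlating biometrics with mode scores over 50
random instances shows every size measurement tracking mode 1
(`R > 0.98`), while the FMA angle does not (`R = 0.09, p = 0.5`):

```r
ce <- correlationExperiment(model, modes = 2, nInstances = 50,
                            measurer = measureFemur, seed = 1)
subset(ce, mode == 1)[, c("biometric", "R", "p")]
#>                 biometric       R         p
#> 1                  length  0.9864  2.77e-39
#> 3        bicondylar_width  1.0000 6.94e-103
#> ...
#> 13              fma_angle  0.0943  5.15e-01
```

`runPipeline()` wires the stages together (correspondence, Procrustes,
PCA, leave-one-out, mode tables, correlation report) and writes a CSV/JSON
artifact bundle plus a MANIFEST with the configuration and seed.

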