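Package: equiSSM
Title: Statistical Shape Modeling and Biometrics of Equine Long Bones
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds point-correspondence statistical shape models (SSM) of
    equine femur and tibia triangle meshes and measures the standard stifle
    biometric suite on model instances. Provides mesh I/O (STL/PLY/OBJ),
    smoothing and isotropic remeshing, similarity-ICP alignment with
    radial-basis warp correspondence, generalized Procrustes analysis, PCA
    modes of variation with compactness and leave-one-out evaluation,
    geometric primitives (least-squares spheres and axes, projected angles,
    discrete Gaussian curvature borders), femoral and tibial biometrics
    (lengths, widths, sphere radii, FMA/neck/version/tubercle angles,
    CTP/CTS angles), mode-biometric correlation experiments, and a
    parametric synthetic bone generator with analytic ground truth so the
    whole pipeline is testable without CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
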