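# direct CorrespondenceSet construction for controlled PCA inputs
corrFromCoords <- function(X, faces = matrix(integer(0), ncol = 3)) {
  new("CorrespondenceSet", coords = X, faces = faces,
      sampleIds = sprintf("s%02d", seq_len(nrow(X))),
      regionLabels = list(), provenance = list())
}

test_that("GPA aligns posed copies to zero residual and centers centroids", {
  set.seed(51)
  base <- matrix(rnorm(60, sd = 20), ncol = 3)
  X <- do.call(rbind, lapply(1:5, function(i) {
    R <- rotationMatrix(rnorm(3), runif(1, 0, 2))
    as.vector(t(sweep(base %*% t(R), 2, -rnorm(3, sd = 30))))
  }))
  al <- generalizedProcrustes(corrFromCoords(X))
  Y <- al@coords
  expect_lt(max(apply(Y, 2, function(c) diff(range(c)))), 1e-6)
  cent <- matrix(Y[1, ], ncol = 3, byrow = TRUE)
  expect_lt(max(abs(colMeans(cent))), 1e-9)
})

test_that("GPA is invariant to a common translation of every sample", {
  set.seed(52)
  X <- matrix(rnorm(5 * 30, sd = 10), nrow = 5)
  shift <- rep(c(100, -50, 30), times = 10)
  a1 <- generalizedProcrustes(corrFromCoords(X))
  a2 <- generalizedProcrustes(corrFromCoords(sweep(X, 2, -shift)))
  expect_lt(max(abs(a1@coords - a2@coords)), 1e-9)
})

test_that("with scale retained, centroid-size variation survives GPA", {
  set.seed(53)
  base <- matrix(rnorm(90, sd = 15), ncol = 3)
  base <- sweep(base, 2, colMeans(base))
  scales <- exp(rnorm(8, 0, 0.08))
  X <- do.call(rbind, lapply(scales, function(s) as.vector(t(s * base))))
  al <- generalizedProcrustes(corrFromCoords(X), removeScale = FALSE)
  sizes <- apply(al@coords, 1, function(r)
    sqrt(sum(matrix(r, ncol = 3, byrow = TRUE)^2)))
  cv0 <- sd(scales) / mean(scales)
  cv1 <- sd(sizes) / mean(sizes)
  expect_lt(abs(cv1 - cv0) / cv0, 0.01)
  # and removeScale = TRUE normalizes size away
  al2 <- generalizedProcrustes(corrFromCoords(X), removeScale = TRUE)
  sizes2 <- apply(al2@coords, 1, function(r)
    sqrt(sum(matrix(r, ncol = 3, byrow = TRUE)^2)))
  expect_lt(sd(sizes2) / mean(sizes2), 1e-6)
})

test_that("pairwise Procrustes agrees with the vegan implementation", {
  set.seed(54)
  A <- matrix(rnorm(45, sd = 10), ncol = 3)
  R <- rotationMatrix(c(1, 0.5, -2), 0.7)
  B <- sweep(A %*% t(R), 2, -c(4, 5, 6)) + matrix(rnorm(45, sd = 0.1),
                                                  ncol = 3)
  vp <- vegan::procrustes(A, B, scale = FALSE) # rotate B onto A
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  k <- equiSSM:::.kabsch(Bc, Ac)
  expect_lt(max(abs(Bc %*% t(k$R) - vp$Yrot)), 1e-8)
})

test_that("PCA of identical shapes has no modes above numerical zero", {
  X <- matrix(rep(rnorm(30, sd = 10), each = 4), nrow = 4)
  m <- fitShapeModel(generalizedProcrustes(corrFromCoords(X)))
  expect_equal(nModes(m), 0)
})

test_that("scale-only variation yields one mode parallel to the mean", {
  st <- scaleOnlyStudy()
  m <- st$model
  cv <- cumulativeVariance(m)
  expect_gt(cv[1], 0.999)
  mode1 <- shapeModes(m)[, 1]
  mu <- meanShape(m) / sqrt(sum(meanShape(m)^2))
  ang <- acos(min(1, abs(sum(mode1 * mu)))) * 180 / pi
  expect_lt(ang, 1)
  # +3SD / -3SD length ratio matches the generative scale ratio within 1%
  truthRatio <- max(c(0.9, 0.95, 1, 1.05, 1.1, 1.15)) /
    min(c(0.9, 0.95, 1, 1.05, 1.1, 1.15))
  hi <- measureFemur(instanceMesh(m, 3))
  lo <- measureFemur(instanceMesh(m, -3))
  r <- biometricValues(hi)["length"] / biometricValues(lo)["length"]
  sdScale <- sd(c(0.9, 0.95, 1, 1.05, 1.1, 1.15))
  expectRatio <- (mean(c(0.9, 0.95, 1, 1.05, 1.1, 1.15)) + 3 * sdScale) /
    (mean(c(0.9, 0.95, 1, 1.05, 1.1, 1.15)) - 3 * sdScale)
  expect_lt(abs(r / expectRatio - 1), 0.01)
})

test_that("training shapes are reconstructed losslessly in the mode span", {
  st <- femurStudy()
  al <- generalizedProcrustes(st$corr)
  m <- fitShapeModel(al)
  for (i in c(1, 7, 15)) {
    x <- al@coords[i, ]
    coef <- crossprod(shapeModes(m), x - meanShape(m))
    recon <- meanShape(m) + shapeModes(m) %*% coef
    expect_lt(max(abs(recon - x)), 1e-6)
  }
})

test_that("instance generation is linear and respects mode bounds", {
  m <- femurStudy()$model
  expect_equal(instanceScores(m), meanShape(m))
  d1 <- instanceScores(m, c(0, 1)) - meanShape(m)
  d2 <- instanceScores(m, c(0, -1)) - meanShape(m)
  expect_equal(d1, -d2)
  expect_error(instanceScores(m, rep(0.5, nModes(m) + 1)), "modes")
  expect_warning(instanceScores(m, 4), "3 SD")
  expect_error(modeRequest(m, nModes(m) + 1, 1), "exceeds")
})

test_that("cumulative variance and 95% mode selection behave analytically", {
  mkModel <- function(vars) {
    n3 <- 3 * (length(vars) + 2)
    Q <- qr.Q(qr(matrix(rnorm(n3 * length(vars)), n3)))
    new("ShapeModel", meanShape = rnorm(n3), modes = Q,
        variances = sort(vars, decreasing = TRUE),
        faces = matrix(integer(0), ncol = 3),
        nSamples = as.integer(length(vars) + 1), regionLabels = list(),
        modeDescriptions = character(0))
  }
  set.seed(56)
  m1 <- mkModel(5)
  expect_equal(cumulativeVariance(m1), 1)
  expect_equal(selectModes(m1), 1L)
  m2 <- mkModel(rep(2, 10))
  expect_equal(cumulativeVariance(m2), (1:10) / 10)
  expect_equal(selectModes(m2, 0.95), ceiling(0.95 * 10))
  # empirical spectrum (100, 5, 1): fractions near the analytic values
  E <- qr.Q(qr(matrix(rnorm(30 * 3), 30)))
  S <- cbind(rnorm(200, 0, 10), rnorm(200, 0, sqrt(5)), rnorm(200, 0, 1))
  X <- S %*% t(E)
  m3 <- fitShapeModel(corrFromCoords(X))
  cv <- cumulativeVariance(m3)[1:3]
  expect_lt(max(abs(cv - c(0.943, 0.991, 1))), 0.05)
})

test_that("PCA is equivariant to a global rotation of all inputs", {
  set.seed(57)
  X <- matrix(rnorm(8 * 30, sd = 5), nrow = 8)
  m0 <- fitShapeModel(generalizedProcrustes(corrFromCoords(X)))
  R <- rotationMatrix(c(2, -1, 1), 1.2)
  Xr <- do.call(rbind, lapply(seq_len(nrow(X)), function(i)
    as.vector(t(matrix(X[i, ], ncol = 3, byrow = TRUE) %*% t(R)))))
  m1 <- fitShapeModel(generalizedProcrustes(corrFromCoords(Xr)))
  expect_lt(max(abs(modeVariances(m0) - modeVariances(m1))) /
              max(modeVariances(m0)), 1e-8)
})

test_that("leave-one-out: identical shapes are predicted by the mean", {
  b <- makeBone(SyntheticBoneParams("femur", meshResolution = 9.5))$mesh
  meshes <- setNames(rep(list(b), 4), sprintf("c%d", 1:4))
  set.seed(58)
  loo <- leaveOneOut(meshes, templateIterations = 1)
  expect_lt(max(loo$surface), 1)
})

test_that("leave-one-out errors shrink with modes and are nested-monotone", {
  st <- femurStudy()
  set.seed(59)
  loo <- fixture("femurLoo", function()
    leaveOneOut(st$meshes, corr = st$corr, maxModes = 8))
  # vertex-space error is exactly non-increasing (nested projections)
  for (i in seq_len(nrow(loo$rmse)))
    expect_true(all(diff(loo$rmse[i, ]) <= 1e-9))
  # the surface-distance curve follows the same trend
  expect_true(all(diff(loo$meanPerModeCount) <= 0.05))
  # one mode must capture most of a scale-dominant population
  expect_lt(loo$meanPerModeCount[2], 0.25 * loo$meanPerModeCount[1])
})
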