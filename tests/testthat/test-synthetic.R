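test_that("generation is deterministic for identical parameters", {
  a <- makeBone(SyntheticBoneParams("femur", meshResolution = 8))
  b <- makeBone(SyntheticBoneParams("femur", meshResolution = 8))
  expect_identical(vertices(a$mesh), vertices(b$mesh))
  expect_identical(faces(a$mesh), faces(b$mesh))
  expect_identical(biometricValues(a$truth), biometricValues(b$truth))
})

test_that("synthetic bones are closed, manifold, genus-0 and labelled", {
  for (bn in list(refFemur(), refTibia())) {
    expect_true(isClosed(bn$mesh))
    chk <- equiSSM:::.edgeManifoldCheck(faces(bn$mesh))
    expect_true(chk$orientable)
    # Euler characteristic 2 (genus 0)
    nE <- nrow(equiSSM:::.edgeTable(faces(bn$mesh)))
    expect_equal(nVertices(bn$mesh) - nE + nFaces(bn$mesh), 2)
    expect_gt(length(regionLabels(bn$mesh)), 4)
    expect_gt(meshVolume(bn$mesh), 0)
  }
})

test_that("scale multiplies every ground-truth length exactly", {
  a <- makeBone(SyntheticBoneParams("tibia", meshResolution = 9))
  b <- makeBone(SyntheticBoneParams("tibia", scale = 1.2,
                                    meshResolution = 9))
  ta <- biometricValues(a$truth)
  tb <- biometricValues(b$truth)
  isdeg <- biometricUnits(a$truth) == "deg"
  expect_equal(unname(tb[!isdeg] / ta[!isdeg]), rep(1.2, sum(!isdeg)),
               tolerance = 1e-12)
  expect_identical(tb[isdeg], ta[isdeg])
})

test_that("parameter validation enforces anatomical plausibility", {
  expect_error(SyntheticBoneParams("femur", neckAngle = 100))
  expect_error(SyntheticBoneParams("femur", scale = 3))
  expect_error(SyntheticBoneParams("tibia", ctsMedial = 15, ctsLateral = 10),
               "lateral slope")
  p <- SyntheticBoneParams("tibia", ctsMedial = 15, ctsLateral = 10,
                           allowInvertedSlopes = TRUE)
  expect_s3_class(p, "SyntheticBoneParams")
})

test_that("population sampling is seeded and matches its specification", {
  pop <- samplePopulation(15, "femur", spec = list(meshResolution = 8),
                          seed = 71)
  pop2 <- samplePopulation(15, "femur", spec = list(meshResolution = 8),
                           seed = 71)
  expect_identical(vapply(pop, function(b) b$params$scale, numeric(1)),
                   vapply(pop2, function(b) b$params$scale, numeric(1)))
  logScales <- log(vapply(pop, function(b) b$params$scale, numeric(1)))
  expect_lt(abs(sd(logScales) - 0.08) / 0.08, 0.3)
  # lateral slope systematically larger than medial
  tib <- samplePopulation(12, "tibia", spec = list(meshResolution = 8),
                          seed = 72)
  offs <- vapply(tib, function(b)
    b$params$ctsLateral - b$params$ctsMedial, numeric(1))
  expect_true(all(offs > 0))
  expect_lt(abs(mean(offs) - 6), 1.5)
})

test_that("a zero-variance population specification collapses the PCA", {
  meshes <- setNames(rep(list(makeBone(SyntheticBoneParams("femur",
    meshResolution = 9.5))$mesh), 4), sprintf("z%d", 1:4))
  set.seed(73)
  corr <- buildCorrespondenceSet(meshes, templateIterations = 1)
  m <- fitShapeModel(generalizedProcrustes(corr))
  tot <- sum(modeVariances(m))
  expect_lt(tot, 1e-6 * sum(meanShape(m)^2))
})

test_that("population statistics do not depend on the draw order", {
  s1 <- samplePopulation(20, "tibia", spec = list(meshResolution = 8),
                         seed = 74)
  s2 <- samplePopulation(20, "tibia", spec = list(meshResolution = 8),
                         seed = 75)
  m1 <- mean(vapply(s1, function(b) b$params$ctsMedial, numeric(1)))
  m2 <- mean(vapply(s2, function(b) b$params$ctsMedial, numeric(1)))
  # two independent seeds agree within sampling error (se ~ 0.8/sqrt(20))
  expect_lt(abs(m1 - m2), 4 * 0.8 / sqrt(20) * sqrt(2))
})
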