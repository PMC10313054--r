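test_that("femur measurements recover the generative ground truth", {
  b <- refFemur()
  m <- measureFemur(b$mesh)
  tv <- biometricValues(b$truth)
  mv <- biometricValues(m)
  isdeg <- biometricUnits(m) == "deg"
  expect_lt(max(abs(mv[isdeg] - tv[isdeg])), 1e-6)
  expect_lt(max(abs(mv[!isdeg] / tv[!isdeg] - 1)), 1e-6)
  expect_setequal(names(mv), c("length", "bicondylar_width",
    "medial_condylar_width", "medial_condylar_depth",
    "medial_condylar_radius", "femoral_head_radius", "fma_angle",
    "neck_angle", "tubercle_angle", "version_angle"))
})

test_that("tibia measurements recover the generative ground truth", {
  b <- refTibia()
  m <- measureTibia(b$mesh)
  tv <- biometricValues(b$truth)
  mv <- biometricValues(m)
  isdeg <- biometricUnits(m) == "deg"
  expect_lt(max(abs(mv[isdeg] - tv[isdeg])), 1e-4)
  expect_lt(max(abs(mv[!isdeg] / tv[!isdeg] - 1)), 1e-6)
  expect_setequal(names(mv), c("length", "bicondylar_width",
    "medial_condylar_width", "medial_condylar_depth", "ctp_angle",
    "cts_medial", "cts_lateral"))
})

test_that("uniform scaling doubles lengths and leaves angles unchanged", {
  b <- refFemur()$mesh
  m0 <- biometricValues(measureFemur(b))
  b2 <- applyTransform(b, SimilarityTransform(scale = 2))
  m2 <- biometricValues(measureFemur(b2))
  isdeg <- biometricUnits(measureFemur(b)) == "deg"
  expect_lt(max(abs(m2[!isdeg] / m0[!isdeg] - 2)), 1e-6)
  expect_lt(max(abs(m2[isdeg] - m0[isdeg])), 1e-6)
})

test_that("measurements are rigid-motion invariant", {
  for (bone in c("femur", "tibia")) {
    b <- if (bone == "femur") refFemur()$mesh else refTibia()$mesh
    measurer <- if (bone == "femur") measureFemur else measureTibia
    m0 <- biometricValues(measurer(b))
    tr <- SimilarityTransform(rotationMatrix(c(0.3, -0.5, 0.81), 1.1),
                              c(100, -50, 30), 1)
    m1 <- biometricValues(measurer(applyTransform(b, tr)))
    expect_lt(max(abs(m1 - m0)), 1e-6)
  }
})

test_that("a mirrored right-side twin measures identically in left convention", {
  b <- refFemur()$mesh
  m0 <- biometricValues(measureFemur(b))
  vm <- vertices(b); vm[, 1] <- -vm[, 1]
  right <- TriangleMesh(vm, faces(b)[, c(1, 3, 2)], regionLabels(b),
                        validate = FALSE)
  m1 <- biometricValues(measureFemur(mirrorToLeft(right, "right")))
  expect_lt(max(abs(m1 - m0)), 1e-6)
})

test_that("missing regions are reported by name", {
  b <- refFemur()$mesh
  regs <- regionLabels(b)
  regs$femoral_head <- NULL
  expect_error(measureFemur(b, regions = regs), "femoral_head")
  rt <- refTibia()$mesh
  regsT <- regionLabels(rt)
  regsT$micet <- integer(0)
  expect_error(measureTibia(rt, regions = regsT), "micet")
})

test_that("a perpendicular zero-slope plateau reads CTP 90 and CTS 0", {
  b <- makeBone(SyntheticBoneParams("tibia", ctpTilt = 0, ctsMedial = 0,
                                    ctsLateral = 0, meshResolution = 8,
                                    allowInvertedSlopes = TRUE))
  m <- biometricValues(measureTibia(b$mesh))
  expect_lt(abs(m["ctp_angle"] - 90), 0.1)
  expect_lt(abs(m["cts_medial"]), 0.1)
  expect_lt(abs(m["cts_lateral"]), 0.1)
})

test_that("the lateral-medial slope offset is recovered across a population", {
  pop <- fixture("tibiaPop10", function()
    samplePopulation(10, "tibia", spec = list(meshResolution = 8),
                     seed = 202))
  diffs <- vapply(pop, function(bn) {
    m <- biometricValues(measureTibia(bn$mesh))
    tv <- biometricValues(bn$truth)
    (m["cts_lateral"] - m["cts_medial"]) -
      (tv["cts_lateral"] - tv["cts_medial"])
  }, numeric(1))
  expect_lt(max(abs(diffs)), 0.5)
})

test_that("mode-range arithmetic follows the stated conventions", {
  vals <- c(400.9, 419.5, 439.3, 460.6, 476.7, 496.5, 515.9)
  s <- modeRangeStats(vals, unit = "mm")
  expect_equal(s$percentIncrease, 100 * (515.9 - 400.9) / 400.9)
  expect_equal(s$percentIncreaseRounded, 29)
  expect_equal(s$rangeWidth, 115, tolerance = 1e-12)
  sa <- modeRangeStats(c(87.1, 88.4, 88.4, 88.9, 89.2, 89.8, 90.5),
                       unit = "deg")
  expect_true(is.na(sa$percentIncrease))
  expect_equal(sa$rangeWidth, 3.4, tolerance = 1e-9)
  sc <- modeRangeStats(rep(5, 7), unit = "mm")
  expect_equal(sc$percentIncrease, 0)
  expect_equal(sc$rangeWidth, 0)
})

test_that("mode-range summaries on a fitted model measure the instances", {
  m <- femurStudy()$model
  s <- modeRangeSummary(m, 1, "length", measureFemur)
  expect_equal(length(s$values), 7)
  expect_true(all(diff(s$values) > 0)) # scaling mode grows every instance
  expect_equal(s$unit, "mm")
  expect_gt(s$percentIncrease, 0)
})

test_that("valgus/varus sign convention", {
  expect_equal(valgusVarus(88.9), 1.1, tolerance = 1e-9)
  expect_equal(valgusVarus(90), 0)
  expect_equal(valgusVarus(91), -1)
})

test_that("biometric recovery regression: slope 1 and tight residuals", {
  bones <- fixture("recoveryBones30", function() {
    set.seed(301)
    c(samplePopulation(15, "femur", spec = list(meshResolution = 8,
        neckSd = 3, versionSd = 3, fmaSd = 1, tubercleSd = 2), seed = 31),
      samplePopulation(15, "tibia", spec = list(meshResolution = 8,
        ctpSd = 0.8, ctsMedialSd = 1.5), seed = 32))
  })
  meas <- NULL
  for (bn in bones) {
    measurer <- if (bn$params$bone == "femur") measureFemur else measureTibia
    mv <- biometricValues(measurer(bn$mesh))
    tv <- biometricValues(bn$truth)
    un <- biometricUnits(bn$truth)
    meas <- rbind(meas, data.frame(bone = bn$params$bone,
                                   biometric = names(mv), unit = un,
                                   measured = unname(mv),
                                   truth = unname(tv)))
  }
  for (key in unique(paste(meas$bone, meas$biometric))) {
    sub <- meas[paste(meas$bone, meas$biometric) == key, ]
    if (sd(sub$truth) < 1e-9) next # constants carry no regression signal
    fit <- lm(measured ~ truth, data = sub)
    expect_lt(abs(coef(fit)[2] - 1), 0.05)
    res <- sub$measured - sub$truth
    if (sub$unit[1] == "deg") {
      expect_lt(sqrt(mean(res^2)), 1)       # < 1 degree RMSE
    } else {
      expect_lt(sqrt(mean((res / sub$truth)^2)), 0.01) # < 1% RMSE
    }
  }
})
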