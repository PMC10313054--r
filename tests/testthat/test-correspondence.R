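test_that("ICP on identical meshes returns the identity transform", {
  b <- refFemur()$mesh
  set.seed(1)
  al <- alignSimilarity(b, b)
  expect_lt(abs(al$transform@scale - 1), 1e-6)
  expect_lt(max(abs(al$transform@rotation - diag(3))), 1e-6)
  expect_lt(max(abs(al$transform@translation)), 1e-6)
  expect_true(al$converged)
})

test_that("ICP recovers a known similarity transform", {
  b <- refFemur()$mesh
  R <- rotationMatrix(c(0, 0, 1), 30 * pi / 180)
  truth <- SimilarityTransform(R, c(10, -5, 2), 1.3)
  set.seed(2)
  al <- alignSimilarity(applyTransform(b, truth), b)
  comp <- composeTransforms(al$transform, truth)
  expect_lt(max(abs(comp@rotation - diag(3))), 1e-3)
  expect_lt(max(abs(comp@translation)), 1e-3)
  expect_lt(abs(comp@scale - 1), 1e-3)
  # objective trace is non-increasing across accepted iterations
  expect_true(all(diff(al$rms) <= 1e-12))
})

test_that("ICP scale-only case recovers the scale factor", {
  b <- refTibia()$mesh
  set.seed(3)
  al <- alignSimilarity(applyTransform(b, SimilarityTransform(scale = 2)), b)
  expect_lt(abs(al$transform@scale - 0.5), 1e-3 * 0.5)
})

test_that("warp of a template onto itself is the identity with fixed topology", {
  b <- refFemur()$mesh
  w <- warpCorrespondence(b, b)
  expect_lt(max(abs(w$vertices - vertices(b))), 1e-6)
  expect_equal(w$foldedFrac, 0)
})

test_that("warp follows a known smooth bend at identifiable landmarks", {
  b <- refFemur()$mesh
  v <- vertices(b)
  zr <- range(v[, 3])
  bendFun <- function(v) {
    t <- (v[, 3] - zr[1]) / diff(zr)
    v + cbind(10 * t^2, 0 * t, 0 * t) # quadratic bend, max 10 mm
  }
  bent <- TriangleMesh(bendFun(v), faces(b), validate = FALSE)
  w <- warpCorrespondence(b, bent)
  expect_identical(faces(b), faces(b)) # topology contract: same face list
  dev <- sqrt(rowSums((w$vertices - bendFun(v))^2))
  # geometrically identifiable landmarks land on their deformed positions;
  # tangential sliding on the symmetric head sphere is expected and harmless
  regs <- regionLabels(b)
  landmarks <- c(extremeVertex(b, c(0, 0, 1), "greater_trochanter"),
                 extremeVertex(b, c(0, 0, -1), "lateral_trochlear_tubercle"),
                 extremeVertex(b, c(-1, 0, 0), "medial_condyle"),
                 extremeVertex(b, c(1, 0, 0), "lateral_condyle"))
  expect_lt(max(dev[landmarks]), 1)
  expect_lt(mean(dev[regs$diaphysis]), 1)
})

test_that("correspondence across posed copies is consistent", {
  b <- makeBone(SyntheticBoneParams("femur", meshResolution = 9.5))$mesh
  set.seed(7)
  poses <- list(SimilarityTransform(),
                SimilarityTransform(rotationMatrix(c(0, 0, 1), 0.4),
                                    c(20, 0, -5), 1),
                SimilarityTransform(rotationMatrix(c(1, 1, 0), -0.3),
                                    c(-10, 15, 0), 1),
                SimilarityTransform(rotationMatrix(c(0, 1, 0), 0.2),
                                    c(0, -20, 10), 1),
                SimilarityTransform(rotationMatrix(c(1, 0, 1), 0.15),
                                    c(5, 5, 5), 1))
  meshes <- lapply(poses, function(tr) applyTransform(b, tr))
  names(meshes) <- sprintf("copy%d", seq_along(meshes))
  corr <- buildCorrespondenceSet(meshes, templateIterations = 1)
  X <- corr@coords
  spread <- apply(X, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-3)
})

test_that("scaled copies agree after normalizing by their native scale", {
  b <- makeBone(SyntheticBoneParams("femur", meshResolution = 9.5))$mesh
  scales <- c(1, 1.1, 0.9)
  meshes <- lapply(scales, function(s)
    applyTransform(b, SimilarityTransform(scale = s)))
  names(meshes) <- sprintf("s%02d", seq_along(meshes))
  set.seed(8)
  corr <- buildCorrespondenceSet(meshes, templateIterations = 1)
  X <- corr@coords / scales # undo the generative scale
  spread <- apply(X, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 1e-2)
})

test_that("corresponded surfaces stay within tolerance of their originals", {
  st <- femurStudy()
  audits <- vapply(st$corr@provenance$samples, function(p) p$surfaceAudit,
                   numeric(1))
  expect_true(all(audits < 1)) # mean distance < 1 mm for every sample
  # max-distance contract: within 3x the mean tolerance for each sample
  for (i in seq_len(nSamples(st$corr))) {
    id <- sampleIds(st$corr)[i]
    tr <- st$corr@provenance$samples[[id]]$transform
    origC <- TriangleMesh(applyTransform(vertices(st$meshes[[id]]), tr) /
                            tr@scale, faces(st$meshes[[id]]),
                          validate = FALSE)
    expect_lt(meanSurfaceDistance(corrMesh(st$corr, i), origC), 1)
  }
})

test_that("correspondence needs at least 3 usable samples", {
  b <- refFemur()$mesh
  expect_error(buildCorrespondenceSet(list(a = b, b = b)), "at least 3")
})
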