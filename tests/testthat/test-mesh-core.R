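test_that("STL round trip welds the unit cube to 8 vertices and 12 faces", {
  cube <- unitCubeMesh()
  p <- withr::local_tempfile(fileext = ".stl")
  saveMesh(cube, p, binary = TRUE)
  m <- suppressWarnings(loadMesh(p))
  expect_equal(nVertices(m), 8)
  expect_equal(nFaces(m), 12)
  p2 <- withr::local_tempfile(fileext = ".stl")
  saveMesh(cube, p2, binary = FALSE)
  m2 <- suppressWarnings(loadMesh(p2))
  expect_equal(nVertices(m2), 8)
})

test_that("write-then-read preserves vertex coordinates per format", {
  s <- icoSphere(40, 2)
  for (fmt in c("ply", "obj")) {
    for (binary in if (fmt == "ply") c(TRUE, FALSE) else FALSE) {
      p <- withr::local_tempfile(fileext = paste0(".", fmt))
      saveMesh(s, p, binary = binary)
      m <- loadMesh(p)
      tolmm <- if (binary) 1e-4 else 1e-6 # float32 vs printed decimals
      expect_lt(max(abs(vertices(m) - vertices(s))), tolmm)
      expect_equal(faces(m), faces(s))
    }
  }
  # STL loses vertex order but not geometry
  p <- withr::local_tempfile(fileext = ".stl")
  saveMesh(s, p)
  m <- suppressWarnings(loadMesh(p))
  expect_lt(meanSurfaceDistance(m, s), 1e-4)
})

test_that("truncated binary STL errors with the byte offset", {
  s <- icoSphere(40, 1)
  p <- withr::local_tempfile(fileext = ".stl")
  saveMesh(s, p, binary = TRUE)
  raw <- readBin(p, "raw", 400)
  p2 <- withr::local_tempfile(fileext = ".stl")
  writeBin(raw, p2)
  expect_error(loadMesh(p2), "truncated.*byte offset")
})

test_that("region annotation JSON round-trips with 0-based indices on disk", {
  regions <- list(head = c(1L, 5L, 9L), shaft = 2:4)
  p <- withr::local_tempfile(fileext = ".json")
  saveRegions(regions, p)
  raw <- jsonlite::fromJSON(p)
  expect_equal(min(unlist(raw)), 0) # 0-based on disk
  expect_equal(loadRegions(p), lapply(regions, as.integer))
})

test_that("mirrorToLeft reflects across x = 0, flips winding, is involutive", {
  mesh <- TriangleMesh(rbind(c(1, 2, 3), c(0, 1, 0), c(0, 0, 1)),
                       matrix(c(1, 2, 3), 1))
  m <- mirrorToLeft(mesh, "right")
  expect_equal(vertices(m)[1, ], c(-1, 2, 3))
  expect_equal(faces(m)[1, ], c(1L, 3L, 2L))
  expect_identical(vertices(mirrorToLeft(mesh, "left")), vertices(mesh))
  twice <- mirrorToLeft(mirrorToLeft(mesh, "right"), "right")
  expect_lt(max(abs(vertices(twice) - vertices(mesh))), 1e-12)
})

test_that("mirroring is an isometry and preserves enclosed volume", {
  b <- refFemur()$mesh
  v <- vertices(b)
  set.seed(4)
  idx <- sample(nVertices(b), 40)
  d0 <- as.matrix(dist(v[idx, ]))
  vm <- vertices(mirrorToLeft(b, "right"))
  d1 <- as.matrix(dist(vm[idx, ]))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  expect_equal(meshVolume(mirrorToLeft(b, "right")), meshVolume(b),
               tolerance = 1e-12)
})

test_that("mean surface distance: identity, analytic offsets, symmetry", {
  s <- icoSphere(20, 3)
  expect_equal(meanSurfaceDistance(s, s), 0)
  # concentric spheres: analytic offset 0.1 with tessellation error bound
  a <- icoSphere(1.0, 4)
  b <- icoSphere(1.1, 4)
  expect_equal(meanSurfaceDistance(a, b), 0.1, tolerance = 0.005 / 0.1)
  # square patch translated along its normal
  patch <- TriangleMesh(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0),
                              c(0, 10, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 4)), validate = FALSE)
  moved <- TriangleMesh(sweep(vertices(patch), 2, c(0, 0, -2)),
                        faces(patch), validate = FALSE)
  expect_equal(meanSurfaceDistance(patch, moved), 2, tolerance = 1e-9)
  # symmetric by construction
  f <- refFemur()$mesh
  t <- TriangleMesh(sweep(vertices(f), 2, c(-3, 2, -1)), faces(f),
                    validate = FALSE)
  expect_equal(meanSurfaceDistance(f, t), meanSurfaceDistance(t, f))
  expect_error(meanSurfaceDistance(TriangleMesh(matrix(numeric(0), ncol = 3),
                                                matrix(integer(0), ncol = 3)),
                                   s), "empty")
})

test_that("TriangleMesh validity rejects bad faces and labels", {
  v <- diag(3)
  expect_error(TriangleMesh(v, matrix(c(1, 2, 4), 1)), "out of vertex range")
  expect_error(TriangleMesh(v, matrix(c(1, 2, 2), 1)), "repeat")
  expect_error(TriangleMesh(v, matrix(c(1, 2, 3), 1),
                            regionLabels = list(a = 5L)), "invalid vertices")
  # duplicated face breaks orientability
  expect_error(TriangleMesh(v, rbind(c(1, 2, 3), c(1, 2, 3))),
               "manifold")
})

test_that("small meshes warn about implausible bone dimensions", {
  p <- withr::local_tempfile(fileext = ".ply")
  saveMesh(icoSphere(2, 1), p)
  expect_warning(loadMesh(p), "assumed mm")
})
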