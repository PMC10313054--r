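test_that("sphere fit recovers exact spheres and flags degenerate input", {
  set.seed(21)
  th <- runif(200, 0, pi)
  ph <- runif(200, 0, 2 * pi)
  p <- cbind(36 * sin(th) * cos(ph) + 1, 36 * sin(th) * sin(ph) + 2,
             36 * cos(th) + 3)
  fit <- fitSphere(p)
  expect_lt(max(abs(fit$center - c(1, 2, 3))), 1e-9)
  expect_lt(abs(fit$radius - 36), 1e-9)
  expect_error(fitSphere(cbind(runif(10), runif(10), 0)), "coplanar")
  expect_error(fitSphere(diag(3)), "4 points")
})

test_that("sphere fit on a noisy hemisphere patch is accurate to 0.05 mm", {
  set.seed(22)
  n <- 500
  th <- acos(runif(n))        # upper hemisphere
  ph <- runif(n, 0, 2 * pi)
  r <- 36
  p <- cbind(r * sin(th) * cos(ph), r * sin(th) * sin(ph), r * cos(th))
  p <- p + matrix(rnorm(3 * n, 0, 0.1), n, 3)
  fit <- fitSphere(p)
  expect_lt(abs(fit$radius - r), 0.05)
  # brute-force oracle: grid refinement of the mean orthogonal residual
  obj <- function(czr) mean((sqrt(rowSums(sweep(p, 2,
    c(0, 0, czr[1]))^2)) - czr[2])^2)
  grid <- expand.grid(cz = seq(-1, 1, 0.02), r = seq(35.5, 36.5, 0.02))
  best <- grid[which.min(apply(grid, 1, obj)), ]
  expect_lt(abs(fit$radius - best$r), 0.05)
})

test_that("axis fit matches exact constructions and flags bowed tubes", {
  d <- c(1, 1, 1) / sqrt(3)
  pts <- outer(seq(0, 100, 5), d)
  fit <- fitAxis(pts)
  expect_lt(acos(min(1, abs(sum(fit$direction * d)))) * 180 / pi, 1e-6)
  # symmetric cylinder rings: direction exact, unflagged
  z <- rep(seq(0, 200, 10), each = 16)
  ph <- rep(2 * pi * (0:15) / 16, times = 21)
  cyl <- cbind(20 * cos(ph), 20 * sin(ph), z)
  fit <- fitAxis(cyl)
  expect_lt(acos(abs(sum(fit$direction * c(0, 0, 1)))) * 180 / pi, 0.1)
  expect_false(fit$flagged)
  # bent cylinder (10 degree bow): direction within 5 degrees of the chord
  bow <- cbind(20 * cos(ph) + (z / 200)^2 * (200 * tan(10 * pi / 180)),
               20 * sin(ph), z)
  chord <- bow[nrow(bow), ] - bow[1, ]
  fitb <- fitAxis(bow)
  expect_lt(acos(abs(sum(fitb$direction * chord / sqrt(sum(chord^2))))) *
              180 / pi, 5)
  # isotropic cloud flagged
  set.seed(5)
  expect_true(fitAxis(matrix(rnorm(300), ncol = 3))$flagged)
})

test_that("extreme vertex: deterministic tie-break and brute-force agreement", {
  cube <- unitCubeMesh()
  top <- extremeVertex(cube, c(0, 0, 1))
  expect_equal(top, 5L) # four top vertices tie; lowest index wins
  expect_error(extremeVertex(cube, c(0, 0, 0)), "zero direction")
  s <- icoSphere(1, 3)
  set.seed(9)
  for (i in 1:10) {
    d <- rnorm(3)
    idx <- extremeVertex(s, d)
    brute <- which.max(vertices(s) %*% d)
    expect_equal(idx, brute)
  }
  expect_error(extremeVertex(cube, c(1, 0, 0), integer(0)), "empty region")
})

test_that("projected angles match an independent Gram-Schmidt computation", {
  expect_equal(projectedAngle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(projectedAngle(c(2, 3, -1), c(2, 3, -1)), 0, tolerance = 1e-5)
  set.seed(31)
  for (i in 1:50) {
    u <- rnorm(3); v <- rnorm(3); n <- rnorm(3); n <- n / sqrt(sum(n^2))
    # oracle: subtract normal components explicitly, use atan2 form
    up <- u - sum(u * n) * n
    vp <- v - sum(v * n) * n
    cr <- c(up[2] * vp[3] - up[3] * vp[2], up[3] * vp[1] - up[1] * vp[3],
            up[1] * vp[2] - up[2] * vp[1])
    oracle <- atan2(sqrt(sum(cr^2)), sum(up * vp)) * 180 / pi
    expect_lt(abs(projectedAngle(u, v, n) - oracle), 1e-9)
  }
  expect_error(projectedAngle(c(0, 0, 1), c(1, 0, 0), c(0, 0, 1)),
               "degenerate")
  expect_equal(lineAngle(c(1, 0, 0), c(-1, 0.001, 0)), 0.0573,
               tolerance = 1e-2)
})

test_that("discrete Gaussian curvature: flat interior, cube corner, sphere", {
  # flat triangulated grid: interior vertices have zero deficit
  g <- expand.grid(x = 0:4, y = 0:4)
  v <- cbind(g$x, g$y, 0)
  idx <- function(i, j) (j - 1) * 5 + i
  f <- NULL
  for (i in 1:4) for (j in 1:4)
    f <- rbind(f, c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
               c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1)))
  gc <- gaussianCurvature(TriangleMesh(v, f, validate = FALSE))
  interior <- !gc$boundary
  expect_true(any(interior))
  expect_lt(max(abs(gc$angleDeficit[interior])), 1e-9)
  # cube corner: angle deficit pi/2
  gc2 <- gaussianCurvature(unitCubeMesh())
  expect_equal(gc2$angleDeficit[1], pi / 2, tolerance = 1e-12)
  # icosphere radius 10: normalized curvature 1/r^2 within 10%
  gc3 <- gaussianCurvature(icoSphere(10, 3))
  expect_equal(mean(gc3$curvature), 0.01, tolerance = 0.1)
})

test_that("Gauss-Bonnet: deficits sum to 4*pi on closed genus-0 fixtures", {
  for (mesh in list(icoSphere(25, 2), refFemur()$mesh, refTibia()$mesh)) {
    gc <- gaussianCurvature(mesh)
    expect_equal(sum(gc$angleDeficit), 4 * pi, tolerance = 1e-6 / (4 * pi))
  }
})

test_that("curvature border isolates the raised eminence on the tibia", {
  b <- refTibia()
  regs <- regionLabels(b$mesh)
  statRegion <- unique(c(regs$plateau_medial, regs$micet))
  cb <- curvatureBorder(b$mesh, statRegion, kSd = 1)
  expect_false(cb$empty)
  # selected border vertices lie on the eminence (ground-truth labels)
  expect_gte(mean(cb$vertices %in% regs$micet), 0.9)
  # monotone in the threshold: kSd = 0 selects a superset
  cb0 <- curvatureBorder(b$mesh, statRegion, kSd = 0)
  expect_true(all(cb$vertices %in% cb0$vertices))
  # homogeneous-curvature region: empty border with warning
  s <- icoSphere(30, 3)
  expect_warning(cbs <- curvatureBorder(s, seq_len(200), kSd = 3),
                 "no vertices exceed")
  expect_true(cbs$empty)
})

test_that("sphere and axis fits are rigid-motion equivariant", {
  set.seed(41)
  th <- runif(120, 0, pi); ph <- runif(120, 0, 2 * pi)
  p <- cbind(15 * sin(th) * cos(ph), 15 * sin(th) * sin(ph), 15 * cos(th))
  R <- rotationMatrix(c(1, 2, 3), 0.8)
  tr <- c(5, -7, 2)
  f0 <- fitSphere(p)
  f1 <- fitSphere(sweep(p %*% t(R), 2, -tr))
  expect_lt(max(abs(f1$center - (as.vector(R %*% f0$center) + tr))), 1e-9)
  expect_lt(abs(f1$radius - f0$radius), 1e-9)
  z <- rep(seq(0, 100, 10), each = 12)
  ph <- rep(2 * pi * (0:11) / 12, times = 11)
  cyl <- cbind(8 * cos(ph), 8 * sin(ph), z)
  a0 <- fitAxis(cyl)
  a1 <- fitAxis(sweep(cyl %*% t(R), 2, -tr))
  expect_lt(acos(abs(sum(a1$direction * as.vector(R %*% a0$direction)))),
            1e-9)
})
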