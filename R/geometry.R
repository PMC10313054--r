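# Geometric primitives used by the biometric constructions: least-squares
# spheres and axes, directional extreme points, projected angles, and
# discrete Gaussian curvature with threshold borders.

#' Least-squares sphere fit
#'
#' Algebraic (Pratt-style linear) initialization followed by geometric
#' Gauss-Newton refinement of the orthogonal distances.
#'
#' @param points n x 3 matrix, n >= 4, not coplanar.
#' @param maxIter Gauss-Newton iterations.
#' @return list with `center` (numeric(3), mm), `radius` (mm) and `rms`
#'   residual (mm).
#' @export
fitSphere <- function(points, maxIter = 25) {
  p <- as.matrix(points)
  if (nrow(p) < 4) stop("fitSphere: need at least 4 points")
  cv <- stats::cov(p)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] < 1e-12 * max(ev[1], 1e-300))
    stop("fitSphere: degenerate input (points are coplanar)")
  # algebraic: |p|^2 = 2 c.p + (R^2 - |c|^2)
  A <- cbind(2 * p, 1)
  b <- rowSums(p^2)
  sol <- qr.solve(A, b)
  ctr <- sol[1:3]
  r <- sqrt(sol[4] + sum(ctr^2))
  # geometric refinement
  for (i in seq_len(maxIter)) {
    d <- sweep(p, 2, ctr)
    len <- sqrt(rowSums(d^2))
    res <- len - r
    J <- cbind(-d / len, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) rep(0, 4))
    ctr <- ctr + step[1:3]
    r <- r + step[4]
    if (sqrt(sum(step^2)) < 1e-12 * max(r, 1)) break
  }
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  list(center = as.double(ctr), radius = r,
       rms = sqrt(mean((d - r)^2)))
}

#' Dominant-spread axis fit
#'
#' Line through the centroid along the direction of maximal spread (first
#' principal direction). For tubular regions such as a diaphysis this
#' approximates the centerline. Near-isotropic clouds (spread ratio < 2) are
#' flagged, not rejected.
#'
#' @param points n x 3 matrix, n >= 3.
#' @param orient optional vector; the returned direction is flipped to have
#'   a positive dot product with it.
#' @return list with `point` (centroid), `direction` (unit), `spreadRatio`
#'   and `flagged` (logical).
#' @export
fitAxis <- function(points, orient = NULL) {
  p <- as.matrix(points)
  if (nrow(p) < 3) stop("fitAxis: need at least 3 points")
  ctr <- colMeans(p)
  e <- eigen(stats::cov(p), symmetric = TRUE)
  dir <- e$vectors[, 1]
  dir <- dir / sqrt(sum(dir^2))
  if (!is.null(orient) && sum(dir * orient) < 0) dir <- -dir
  ratio <- sqrt(max(e$values[1], 0) / max(e$values[2], 1e-300))
  list(point = as.double(ctr), direction = as.double(dir),
       spreadRatio = ratio, flagged = ratio < 2)
}

#' Cylinder-axis estimate from surface normals
#'
#' For a tubular surface patch every face normal is perpendicular to the
#' tube axis, so the axis is the least-variance direction of the
#' area-weighted face-normal covariance. Unlike the dominant-spread point
#' fit this is insensitive to uneven sampling along the patch, which makes
#' it the estimator of choice for diaphysis and neck axes on remeshed or
#' corresponded surfaces.
#'
#' @param mesh a [TriangleMesh-class].
#' @param region region name or integer vertex indices; only faces whose
#'   three corners all belong to the region contribute.
#' @param orient optional vector fixing the direction sign.
#' @return list with `point` (region centroid), `direction` (unit vector)
#'   and `nFaces` used.
#' @export
fitAxisNormals <- function(mesh, region, orient = NULL) {
  idx <- .resolveRegion(mesh, region)
  f <- faces(mesh)
  inReg <- matrix(f %in% idx, nrow(f))
  use <- rowSums(inReg) == 3
  if (sum(use) < 3) stop("fitAxisNormals: fewer than 3 interior faces")
  cr <- .faceCross(vertices(mesh), f[use, , drop = FALSE])
  a <- sqrt(rowSums(cr^2))
  n <- cr / a
  M <- crossprod(n * sqrt(a)) # area-weighted normal scatter
  e <- eigen(M, symmetric = TRUE)
  dir <- e$vectors[, 3]
  if (!is.null(orient) && sum(dir * orient) < 0) dir <- -dir
  list(point = colMeans(vertices(mesh)[idx, , drop = FALSE]),
       direction = as.double(dir), nFaces = sum(use))
}

#' Extreme vertex along a direction
#'
#' The vertex (optionally restricted to a region) maximizing the dot product
#' with `direction`; ties are broken deterministically by lowest index.
#'
#' @param mesh a [TriangleMesh-class].
#' @param direction a nonzero direction vector.
#' @param withinRegion optional region name (from `regionLabels(mesh)`) or an
#'   integer vertex-index vector.
#' @return the vertex index (into `vertices(mesh)`).
#' @export
extremeVertex <- function(mesh, direction, withinRegion = NULL) {
  if (sqrt(sum(direction^2)) < 1e-300)
    stop("extremeVertex: zero direction vector")
  idx <- .resolveRegion(mesh, withinRegion)
  if (!length(idx)) stop("extremeVertex: empty region")
  s <- as.vector(vertices(mesh)[idx, , drop = FALSE] %*% direction)
  idx[which.max(s)] # which.max returns the first (lowest-index) maximum
}

.resolveRegion <- function(mesh, region) {
  if (is.null(region)) return(seq_len(nVertices(mesh)))
  if (is.character(region)) {
    if (length(region) == 1 && !region %in% names(regionLabels(mesh)))
      stop("unknown region: ", region)
    return(sort(unique(unlist(regionLabels(mesh)[region]))))
  }
  as.integer(region)
}

#' Unsigned angle between two vectors, optionally in a projection plane
#'
#' With `planeNormal` given, both vectors are first projected onto the plane
#' through the origin with that normal (the paper's coronal / sagittal /
#' transverse view constructions); the unsigned angle in degrees in
#' \code{[0, 180]} is returned.
#'
#' @param u,v nonzero vectors.
#' @param planeNormal optional unit normal of the projection plane.
#' @return angle in degrees.
#' @export
projectedAngle <- function(u, v, planeNormal = NULL) {
  if (!is.null(planeNormal)) {
    n <- planeNormal / sqrt(sum(planeNormal^2))
    u <- u - sum(u * n) * n
    v <- v - sum(v * n) * n
  }
  lu <- sqrt(sum(u^2))
  lv <- sqrt(sum(v^2))
  if (lu < 1e-12 || lv < 1e-12)
    stop("projectedAngle: degenerate (zero or annihilated) vector")
  acos(pmin(1, pmax(-1, sum(u * v) / (lu * lv)))) * 180 / pi
}

#' @rdname projectedAngle
#' @details `lineAngle` treats both arguments as undirected lines and folds
#'   the result into \code{[0, 90]} degrees.
#' @export
lineAngle <- function(u, v, planeNormal = NULL) {
  a <- projectedAngle(u, v, planeNormal)
  min(a, 180 - a)
}

#' Discrete Gaussian curvature (angle deficit over mixed area)
#'
#' At each interior vertex the Gaussian curvature is estimated as the angle
#' deficit \code{2*pi - sum(incident triangle angles)} normalized by the
#' mixed Voronoi area (Meyer et al. finite-element region, with the standard
#' obtuse-triangle fallback). Boundary vertices are flagged and their deficit
#' is not meaningful. On a closed mesh the raw deficits sum to \code{2*pi}
#' times the Euler characteristic (Gauss-Bonnet).
#'
#' @param mesh a manifold [TriangleMesh-class].
#' @return list with `curvature` (1/mm^2), `angleDeficit` (radians),
#'   `mixedArea` (mm^2) and `boundary` (logical), one entry per vertex.
#' @export
gaussianCurvature <- function(mesh) {
  v <- vertices(mesh)
  f <- faces(mesh)
  nv <- nrow(v)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  lab2 <- rowSums((a - b)^2) # squared edge lengths, opposite c
  lbc2 <- rowSums((b - c)^2) # opposite a
  lca2 <- rowSums((c - a)^2) # opposite b
  angA <- acos(pmin(1, pmax(-1, (lab2 + lca2 - lbc2) /
                              (2 * sqrt(lab2 * lca2)))))
  angB <- acos(pmin(1, pmax(-1, (lab2 + lbc2 - lca2) /
                              (2 * sqrt(lab2 * lbc2)))))
  angC <- pi - angA - angB
  area <- sqrt(rowSums(.faceCross(v, f)^2)) / 2
  # mixed Voronoi area contributions (Meyer): non-obtuse triangles get the
  # cotangent Voronoi cell, obtuse ones area/2 at the obtuse corner, area/4
  # at the others.
  cotA <- 1 / tan(pmax(angA, 1e-12))
  cotB <- 1 / tan(pmax(angB, 1e-12))
  cotC <- 1 / tan(pmax(angC, 1e-12))
  obtuse <- pmax(angA, pmax(angB, angC)) > pi / 2
  vorA <- (lab2 * cotC + lca2 * cotB) / 8
  vorB <- (lab2 * cotC + lbc2 * cotA) / 8
  vorC <- (lca2 * cotB + lbc2 * cotA) / 8
  mixA <- ifelse(obtuse, ifelse(angA > pi / 2, area / 2, area / 4), vorA)
  mixB <- ifelse(obtuse, ifelse(angB > pi / 2, area / 2, area / 4), vorB)
  mixC <- ifelse(obtuse, ifelse(angC > pi / 2, area / 2, area / 4), vorC)
  angleSum <- as.vector(rowsum(c(angA, angB, angC),
                               c(f[, 1], f[, 2], f[, 3]),
                               reorder = TRUE))
  idx <- sort(unique(as.vector(f)))
  fullAngle <- numeric(nv)
  fullArea <- numeric(nv)
  fullAngle[idx] <- angleSum
  fullArea[idx] <- as.vector(rowsum(c(mixA, mixB, mixC),
                                    c(f[, 1], f[, 2], f[, 3]),
                                    reorder = TRUE))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  keyu <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  once <- names(which(table(keyu) == 1))
  boundary <- logical(nv)
  if (length(once)) {
    bidx <- unique(as.integer(unlist(strsplit(once, " "))))
    boundary[bidx] <- TRUE
  }
  deficit <- 2 * pi - fullAngle
  curv <- ifelse(fullArea > 0, deficit / fullArea, NA_real_)
  list(curvature = curv, angleDeficit = deficit, mixedArea = fullArea,
       boundary = boundary)
}

#' Curvature-threshold border detection
#'
#' Selects the vertices of a region whose discrete Gaussian curvature
#' exceeds \code{mean + kSd * SD} (statistics over the region, mesh-boundary
#' vertices excluded), the rule used to separate the medial tibial plateau
#' from the intercondylar eminence. The dividing line runs through the
#' selected border, perpendicular to the caudal-to-cranial direction.
#'
#' @param mesh a [TriangleMesh-class].
#' @param region region name or integer vertex indices (>= 10 vertices).
#' @param kSd threshold multiplier (default 1).
#' @param craniocaudal caudal-to-cranial direction used to orient the
#'   dividing line; when NULL the line is left undefined.
#' @param surfaceNormal approximate surface normal of the region (used with
#'   `craniocaudal` to place the line in the surface plane); defaults to the
#'   smallest-spread direction of the region.
#' @param smoothPasses optional Laplacian smoothing passes applied to the
#'   curvature field before thresholding (default 0).
#' @return list with `vertices` (selected indices), `threshold`,
#'   `linePoint`, `lineDirection` and `empty` (logical warning flag).
#' @export
curvatureBorder <- function(mesh, region, kSd = 1, craniocaudal = NULL,
                            surfaceNormal = NULL, smoothPasses = 0) {
  idx <- .resolveRegion(mesh, region)
  if (length(idx) < 10) stop("curvatureBorder: region must have >= 10 vertices")
  gc <- gaussianCurvature(mesh)
  curv <- gc$curvature
  if (smoothPasses > 0) {
    adj <- .vertexAdjacency(faces(mesh), nVertices(mesh))
    for (i in seq_len(smoothPasses)) {
      sm <- vapply(seq_along(curv), function(k) {
        nb <- adj[[k]]
        if (length(nb)) mean(curv[c(k, nb)], na.rm = TRUE) else curv[k]
      }, numeric(1))
      curv <- sm
    }
  }
  use <- idx[!gc$boundary[idx] & is.finite(curv[idx])]
  mu <- mean(curv[use])
  sdv <- stats::sd(curv[use])
  thr <- mu + kSd * sdv
  sel <- use[curv[use] > thr]
  if (!length(sel)) {
    warning("curvatureBorder: no vertices exceed mean + ", kSd, " SD")
    return(list(vertices = integer(0), threshold = thr, linePoint = NULL,
                lineDirection = NULL, empty = TRUE))
  }
  pts <- vertices(mesh)[sel, , drop = FALSE]
  ctr <- colMeans(pts)
  lineDir <- NULL
  if (!is.null(craniocaudal)) {
    if (is.null(surfaceNormal)) {
      e <- eigen(stats::cov(vertices(mesh)[idx, , drop = FALSE]),
                 symmetric = TRUE)
      surfaceNormal <- e$vectors[, 3]
    }
    d <- craniocaudal / sqrt(sum(craniocaudal^2))
    n <- surfaceNormal / sqrt(sum(surfaceNormal^2))
    lineDir <- c(d[2] * n[3] - d[3] * n[2],
                 d[3] * n[1] - d[1] * n[3],
                 d[1] * n[2] - d[2] * n[1])
    lineDir <- lineDir / sqrt(sum(lineDir^2))
  }
  list(vertices = sel, threshold = thr, linePoint = as.double(ctr),
       lineDirection = lineDir, empty = FALSE)
}

# vertex -> neighbouring vertex indices
.vertexAdjacency <- function(f, nv) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)],
             f[, c(2, 1)], f[, c(3, 2)], f[, c(1, 3)])
  split(e[, 2], factor(e[, 1], levels = seq_len(nv)))
}
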