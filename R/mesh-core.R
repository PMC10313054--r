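#' Construct a validated TriangleMesh
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates (mm).
#' @param faces integer f x 3 matrix of 1-based vertex indices.
#' @param regionLabels optional named list of integer vertex-index vectors.
#' @param validate check edge-manifoldness and orientability (default TRUE).
#'   Non-manifold meshes beyond repair raise an error with diagnostics.
#' @return a [TriangleMesh-class] object.
#' @export
TriangleMesh <- function(vertices, faces, regionLabels = list(),
                         validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  colnames(vertices) <- NULL
  colnames(faces) <- NULL
  m <- new("TriangleMesh", vertices = vertices, faces = faces,
           regionLabels = regionLabels)
  if (validate && nrow(faces) > 0) {
    chk <- .edgeManifoldCheck(faces)
    if (!chk$orientable)
      stop("mesh is not manifold-orientable: ", chk$diagnostic)
  }
  m
}

# Edge-use audit: in an orientable edge-manifold triangulation every
# undirected edge is used by at most two faces, and each directed edge at
# most once (consistent winding). Boundary edges (single use) are allowed.
.edgeManifoldCheck <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  keyd <- paste(e[, 1], e[, 2])
  keyu <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  dup <- any(duplicated(keyd))
  cnt <- table(keyu)
  over <- sum(cnt > 2)
  list(orientable = !dup && over == 0,
       boundaryEdges = sum(cnt == 1),
       diagnostic = if (dup) "repeated directed edge (inconsistent winding or duplicate face)"
                    else if (over > 0) sprintf("%d edges shared by >2 faces", over)
                    else "ok")
}

#' Is a mesh closed (watertight)?
#' @param mesh a [TriangleMesh-class].
#' @return logical.
#' @export
isClosed <- function(mesh) {
  .edgeManifoldCheck(faces(mesh))$boundaryEdges == 0
}

# Per-face un-normalized normals (cross products); rows align with faces.
.faceCross <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c <- v[f[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Face areas, enclosed volume and mean edge length
#'
#' `meshVolume` uses the divergence theorem on a closed, consistently wound
#' mesh; `meshArea` sums triangle areas; `edgeLengths` returns every unique
#' undirected edge length.
#' @param mesh a [TriangleMesh-class].
#' @return numeric scalar (`meshVolume`, `meshArea`) or vector
#'   (`edgeLengths`).
#' @export
meshVolume <- function(mesh) {
  v <- vertices(mesh)
  f <- faces(mesh)
  cr <- .faceCross(v, f)
  a <- v[f[, 1], , drop = FALSE]
  sum(rowSums(a * cr)) / 6
}

#' @rdname meshVolume
#' @export
meshArea <- function(mesh) {
  sum(sqrt(rowSums(.faceCross(vertices(mesh), faces(mesh))^2))) / 2
}

#' @rdname meshVolume
#' @export
edgeLengths <- function(mesh) {
  f <- faces(mesh)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  v <- vertices(mesh)
  sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
}

#' Remove zero-area faces and unreferenced vertices
#' @param mesh a [TriangleMesh-class].
#' @param areaTol faces with area below this (mm^2) are dropped.
#' @return a cleaned [TriangleMesh-class]; region labels are remapped.
#' @export
dropDegenerateFaces <- function(mesh, areaTol = 1e-12) {
  f <- faces(mesh)
  areas <- sqrt(rowSums(.faceCross(vertices(mesh), f)^2)) / 2
  keep <- areas > areaTol
  .rebuildMesh(vertices(mesh), f[keep, , drop = FALSE], regionLabels(mesh))
}

# Drop unreferenced vertices, remap faces and labels.
.rebuildMesh <- function(v, f, labels = list()) {
  used <- sort(unique(as.vector(f)))
  map <- integer(nrow(v))
  map[used] <- seq_along(used)
  f2 <- matrix(map[f], ncol = 3)
  labels2 <- lapply(labels, function(idx) {
    idx <- idx[idx %in% used]
    sort(map[idx])
  })
  TriangleMesh(v[used, , drop = FALSE], f2, labels2, validate = FALSE)
}

#' Weld coincident vertices
#'
#' Merges vertices closer than `tol` (snap-to-grid), as needed after reading
#' STL files which store each triangle independently.
#' @param mesh a [TriangleMesh-class].
#' @param tol welding tolerance in mm.
#' @return a [TriangleMesh-class] with shared vertices.
#' @export
weldVertices <- function(mesh, tol = 1e-6) {
  v <- vertices(mesh)
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  f2 <- matrix(map[faces(mesh)], ncol = 3)
  keep <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  TriangleMesh(v2, f2[keep, , drop = FALSE], validate = FALSE)
}

#' Mirror a bone into left-limb convention
#'
#' Right-side bones are reflected across the x = 0 plane of the raw
#' coordinate frame and the face winding is flipped so outward normals are
#' preserved; left-side bones pass through unchanged. The exact mirror plane
#' is immaterial because all subsequent model building removes pose.
#'
#' @param mesh a [TriangleMesh-class].
#' @param side "left" or "right".
#' @return a [TriangleMesh-class] in left-limb convention.
#' @export
mirrorToLeft <- function(mesh, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "left") return(mesh)
  v <- vertices(mesh)
  v[, 1] <- -v[, 1]
  f <- faces(mesh)[, c(1, 3, 2), drop = FALSE]
  TriangleMesh(v, f, regionLabels(mesh), validate = FALSE)
}

#' Closest points on a mesh surface
#'
#' Exact point-to-triangle closest points for a set of query points.
#' @param points numeric n x 3 matrix of query points (mm).
#' @param mesh target [TriangleMesh-class].
#' @return list with `point` (n x 3 closest surface points), `distance`
#'   (n distances, mm) and `face` (supporting face index).
#' @export
closestPointOnSurface <- function(points, mesh) {
  points <- matrix(as.double(points), ncol = 3)
  .cppClosestOnMesh(points, vertices(mesh), faces(mesh))
}

#' Mean surface distance between two meshes
#'
#' Symmetric by default: the mean of vertex-to-surface distances from `a` to
#' `b` and from `b` to `a`, averaged. This is the part-comparison metric used
#' to score correspondence fidelity and leave-one-out reconstruction.
#'
#' @param a,b [TriangleMesh-class] objects.
#' @param direction "symmetric" (default), "a_to_b" or "b_to_a".
#' @return mean distance in mm.
#' @export
meanSurfaceDistance <- function(a, b,
    direction = c("symmetric", "a_to_b", "b_to_a")) {
  direction <- match.arg(direction)
  if (nVertices(a) == 0 || nVertices(b) == 0)
    stop("meanSurfaceDistance: empty mesh")
  dab <- function() mean(closestPointOnSurface(vertices(a), b)$distance)
  dba <- function() mean(closestPointOnSurface(vertices(b), a)$distance)
  switch(direction,
         symmetric = (dab() + dba()) / 2,
         a_to_b = dab(),
         b_to_a = dba())
}

#' Maximum (Hausdorff-style, vertex-sampled) surface distance
#' @inheritParams meanSurfaceDistance
#' @return max vertex-to-surface distance over both directions, mm.
#' @export
maxSurfaceDistance <- function(a, b) {
  max(closestPointOnSurface(vertices(a), b)$distance,
      closestPointOnSurface(vertices(b), a)$distance)
}

#' Construct an AnatomicalFrame
#'
#' Axes are re-orthogonalized: PD is kept, ML is made orthogonal to PD, and
#' CrCd completes the right-handed (ML, CrCd, PD) triad.
#' @param origin numeric(3) origin, mm.
#' @param PD proximal-to-distal direction.
#' @param ML approximate medial-to-lateral direction.
#' @return an [AnatomicalFrame-class].
#' @export
AnatomicalFrame <- function(origin, PD, ML) {
  pd <- PD / sqrt(sum(PD^2))
  ml <- ML - sum(ML * pd) * pd
  ml <- ml / sqrt(sum(ml^2))
  crcd <- c(pd[2] * ml[3] - pd[3] * ml[2],
            pd[3] * ml[1] - pd[1] * ml[3],
            pd[1] * ml[2] - pd[2] * ml[1])
  new("AnatomicalFrame", origin = as.double(origin), ML = ml, CrCd = crcd,
      PD = pd)
}

#' Construct / apply a SimilarityTransform
#'
#' `applyTransform` maps vertices v to `scale * R v + t`.
#' @param rotation 3x3 rotation matrix.
#' @param translation numeric(3), mm.
#' @param scale positive scalar.
#' @return a [SimilarityTransform-class].
#' @export
SimilarityTransform <- function(rotation = diag(3),
                                translation = c(0, 0, 0), scale = 1) {
  new("SimilarityTransform", rotation = rotation,
      translation = as.double(translation), scale = as.double(scale))
}

#' @rdname SimilarityTransform
#' @param mesh a [TriangleMesh-class] (or n x 3 matrix of points).
#' @param transform a [SimilarityTransform-class].
#' @export
applyTransform <- function(mesh, transform) {
  tp <- function(v) sweep(transform@scale * v %*% t(transform@rotation), 2,
                          -transform@translation)
  if (is(mesh, "TriangleMesh")) {
    TriangleMesh(tp(vertices(mesh)), faces(mesh), regionLabels(mesh),
                 validate = FALSE)
  } else {
    tp(as.matrix(mesh))
  }
}

#' @rdname SimilarityTransform
#' @param a,b [SimilarityTransform-class]s; returns the transform equivalent
#'   to applying `b` first, then `a`.
#' @export
composeTransforms <- function(a, b) {
  SimilarityTransform(rotation = a@rotation %*% b@rotation,
                      translation = a@scale * as.vector(a@rotation %*% b@translation) +
                        a@translation,
                      scale = a@scale * b@scale)
}
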