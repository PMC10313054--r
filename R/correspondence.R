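# Dense point-to-point correspondence: similarity ICP alignment of each
# sample to a template, a coarse-to-fine radial-basis warp of the template
# onto the aligned sample, and the two-pass scheme in which the PCA mean of
# the first pass becomes the template of the second.

# Umeyama closed-form similarity solve mapping paired points X -> Y.
.umeyama <- function(X, Y, withScale = TRUE) {
  mx <- colMeans(X)
  my <- colMeans(Y)
  Xc <- sweep(X, 2, mx)
  Yc <- sweep(Y, 2, my)
  S <- crossprod(Yc, Xc) / nrow(X)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  s <- if (withScale) sum(diag(D) * sv$d) / mean(rowSums(Xc^2)) else 1
  t <- my - s * as.vector(R %*% mx)
  SimilarityTransform(rotation = R, translation = t, scale = s)
}

# candidate initializations: centroid/scale match with principal-axis
# rotations (4 proper sign combinations) plus the identity rotation
.icpInitCandidates <- function(Vs, Vt) {
  ms <- colMeans(Vs)
  mt <- colMeans(Vt)
  ss <- sqrt(mean(rowSums(sweep(Vs, 2, ms)^2)))
  st <- sqrt(mean(rowSums(sweep(Vt, 2, mt)^2)))
  s0 <- st / ss
  Es <- eigen(stats::cov(Vs), symmetric = TRUE)$vectors
  Et <- eigen(stats::cov(Vt), symmetric = TRUE)$vectors
  if (det(Es) < 0) Es[, 3] <- -Es[, 3]
  if (det(Et) < 0) Et[, 3] <- -Et[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  cands <- lapply(signs, function(sg) {
    R <- Et %*% diag(sg) %*% t(Es)
    SimilarityTransform(R, mt - s0 * as.vector(R %*% ms), s0)
  })
  c(cands, list(SimilarityTransform(diag(3), mt - s0 * ms, s0)))
}

#' Similarity alignment of a sample mesh to a template (ICP)
#'
#' Iterative closest point over rotation, translation and uniform scale.
#' Each iteration matches a random subset (`sampleFraction` of the sample
#' vertices) to its closest points on the template surface and solves the
#' closed-form similarity; an update is accepted only if the full-vertex RMS
#' distance decreases, so the reported objective is non-increasing across
#' accepted iterations. Initialization tries principal-axis alignments and
#' keeps the best.
#'
#' @param sample,template [TriangleMesh-class] objects.
#' @param sampleFraction fraction of sample vertices matched per iteration,
#'   in (0, 1].
#' @param maxIters iteration cap.
#' @param withScale estimate uniform scale (default TRUE).
#' @param convergedRms alignment is flagged unconverged (a warning, not an
#'   error) if the final RMS exceeds this; defaults to half the template
#'   bounding-box diagonal.
#' @return list with `transform` ([SimilarityTransform-class]), `mesh` (the
#'   transformed sample), `rms` (accepted objective trace, mm),
#'   `iterations`, and `converged`.
#' @export
alignSimilarity <- function(sample, template, sampleFraction = 0.75,
                            maxIters = 50, withScale = TRUE,
                            convergedRms = NULL) {
  stopifnot(sampleFraction > 0, sampleFraction <= 1)
  if (nVertices(sample) == 0 || nVertices(template) == 0)
    stop("alignSimilarity: empty mesh")
  Vs <- vertices(sample)
  Vt <- vertices(template)
  if (is.null(convergedRms)) {
    rng <- apply(Vt, 2, range)
    convergedRms <- sqrt(sum((rng[2, ] - rng[1, ])^2)) / 2
  }
  # acceptance objective on a fixed, deterministic vertex subset (the
  # random per-iteration subset drives the update; this one scores it)
  evalIdx <- unique(round(seq(1, nrow(Vs), length.out = min(nrow(Vs), 600))))
  objective <- function(tr) {
    mean(closestPointOnSurface(applyTransform(Vs[evalIdx, , drop = FALSE], tr),
                               template)$distance^2)
  }
  cands <- .icpInitCandidates(Vs, Vt)
  objs <- vapply(cands, objective, numeric(1))
  tr <- cands[[which.min(objs)]]
  best <- min(objs)
  trace <- sqrt(best)
  n <- nrow(Vs)
  k <- max(4, round(sampleFraction * n))
  rejects <- 0
  iters <- 0
  for (it in seq_len(maxIters)) {
    iters <- it
    sub <- if (k >= n) seq_len(n) else sample.int(n, k)
    cur <- applyTransform(Vs[sub, , drop = FALSE], tr)
    # nearest-vertex matches drive the update (cheap); the acceptance
    # objective below is still measured against the template surface
    m <- .cppNearestPoint(cur, Vt)
    cand <- .umeyama(Vs[sub, , drop = FALSE], Vt[m$index, , drop = FALSE],
                     withScale = withScale)
    o <- objective(cand)
    if (o < best - 1e-14) {
      improved <- (best - o) > 1e-4 * max(best, 1e-12)
      tr <- cand
      best <- o
      trace <- c(trace, sqrt(best))
      rejects <- if (improved) 0 else rejects + 1
    } else {
      rejects <- rejects + 1
    }
    if (rejects >= 3) break
  }
  converged <- sqrt(best) <= convergedRms
  if (!converged)
    warning("alignSimilarity: final RMS ", sprintf("%.2f", sqrt(best)),
            " mm exceeds ", sprintf("%.2f", convergedRms), " mm")
  list(transform = tr, mesh = applyTransform(sample, tr), rms = trace,
       iterations = iters, converged = converged)
}

#' Non-rigid warp of a template onto an aligned sample
#'
#' Coarse-to-fine Gaussian radial-basis deformation driven by mutually
#' nearest vertex pairs, followed by exact closest-point projection onto the
#' sample surface. The output has the template's topology (the face list is
#' untouched) with vertices on the sample surface.
#'
#' @param template [TriangleMesh-class] providing the topology.
#' @param alignedSample [TriangleMesh-class] already similarity-aligned to
#'   the template.
#' @param kernelWidths Gaussian kernel widths per level as fractions of the
#'   template bounding-box diagonal (coarse to fine).
#' @param maxControl control-point budget per level.
#' @param ridge ridge regularization added to the RBF system.
#' @param maxFoldedFrac registration fails if more than this fraction of
#'   faces invert their normal (default 0.01).
#' @return list with `vertices` (template-topology vertex matrix on the
#'   sample surface), `meanDist` (pre-projection mean distance to the sample
#'   surface, mm) and `foldedFrac`.
#' @export
warpCorrespondence <- function(template, alignedSample,
                               kernelWidths = c(0.4, 0.15, 0.06),
                               maxControl = c(60, 200, 500),
                               ridge = 1e-4, maxFoldedFrac = 0.01) {
  Vt <- vertices(template)
  Vs <- vertices(alignedSample)
  rng <- apply(Vt, 2, range)
  diag <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  cur <- Vt
  for (lev in seq_along(kernelWidths)) {
    sigma <- kernelWidths[lev] * diag
    # mutually nearest vertex pairs between the deforming template and the
    # sample; deterministic (no RNG)
    fwd <- .cppNearestPoint(cur, Vs)$index
    bwd <- .cppNearestPoint(Vs, cur)$index
    mutual <- which(bwd[fwd] == seq_len(nrow(cur)))
    if (length(mutual) < 8) next
    nc <- min(maxControl[min(lev, length(maxControl))], length(mutual))
    ctrl <- mutual[unique(round(seq(1, length(mutual), length.out = nc)))]
    X <- cur[ctrl, , drop = FALSE]
    D <- Vs[fwd[ctrl], , drop = FALSE] - X
    K <- exp(-(as.matrix(stats::dist(X))^2) / (2 * sigma^2))
    W <- solve(K + ridge * nrow(K) * diag(nrow(K)), D)
    d2 <- .crossDist2(cur, X)
    cur <- cur + exp(-d2 / (2 * sigma^2)) %*% W
  }
  proj <- closestPointOnSurface(cur, alignedSample)
  meanDist <- mean(proj$distance)
  out <- proj$point
  # fold check: face normals before vs after
  n0 <- .faceCross(Vt, faces(template))
  n1 <- .faceCross(out, faces(template))
  folded <- mean(rowSums(n0 * n1) < 0)
  if (folded > maxFoldedFrac)
    stop(sprintf("warpCorrespondence: %.1f%% of faces inverted (limit %.1f%%)",
                 100 * folded, 100 * maxFoldedFrac))
  list(vertices = out, meanDist = meanDist, foldedFrac = folded)
}

.crossDist2 <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  outer(a2, b2, "+") - 2 * A %*% t(B)
}

#' Build a correspondence set across a bone population
#'
#' Pass one registers every sample to a designated template (similarity ICP
#' then radial-basis warp); the Procrustes/PCA mean of pass one becomes the
#' template for pass two (and so on for `templateIterations` passes), which
#' removes the bias of the arbitrary initial template. Each sample's
#' registration scale is inverted after warping so that native size re-enters
#' the model and the leading mode can capture scaling.
#'
#' @param samples list of [TriangleMesh-class] objects (>= 3).
#' @param templateIndex index of the pass-one template; default the sample
#'   with the median vertex count.
#' @param templateIterations number of template passes (default 2).
#' @param epsCorr mean surface-distance tolerance (mm) for accepting a
#'   corresponded sample (default 1.0).
#' @param sampleFraction,maxIters passed to [alignSimilarity()].
#' @return a [CorrespondenceSet-class]; rejected samples are reported in
#'   `provenance(x)$rejected`.
#' @export
buildCorrespondenceSet <- function(samples, templateIndex = NULL,
                                   templateIterations = 2, epsCorr = 1.0,
                                   sampleFraction = 0.75, maxIters = 50) {
  if (length(samples) < 3)
    stop("buildCorrespondenceSet: need at least 3 samples")
  if (is.null(names(samples)))
    names(samples) <- sprintf("sample%02d", seq_along(samples))
  if (is.null(templateIndex)) {
    nv <- vapply(samples, nVertices, numeric(1))
    templateIndex <- which.min(abs(nv - stats::median(nv)))
  }
  template <- samples[[templateIndex]]
  templLabels <- regionLabels(template)
  perSample <- NULL
  for (pass in seq_len(templateIterations)) {
    coords <- NULL
    keep <- character(0)
    perSample <- list()
    for (nm in names(samples)) {
      res <- tryCatch({
        al <- alignSimilarity(samples[[nm]], template,
                              sampleFraction = sampleFraction,
                              maxIters = maxIters)
        wp <- warpCorrespondence(template, al$mesh)
        # invert the registration scale so native size survives into PCA
        vnat <- wp$vertices / al$transform@scale
        audit <- meanSurfaceDistance(
          TriangleMesh(wp$vertices, faces(template), validate = FALSE),
          al$mesh)
        if (audit > epsCorr)
          stop(sprintf("correspondence audit %.2f mm exceeds epsCorr %.2f mm",
                       audit, epsCorr))
        list(vnat = vnat, prov = list(
          icpRms = al$rms[length(al$rms)], icpIterations = al$iterations,
          icpConverged = al$converged, scale = al$transform@scale,
          transform = al$transform,
          warpMeanDist = wp$meanDist, foldedFrac = wp$foldedFrac,
          surfaceAudit = audit))
      }, error = function(e) e)
      if (inherits(res, "error")) {
        perSample[[nm]] <- list(rejected = TRUE,
                                reason = conditionMessage(res))
      } else {
        coords <- rbind(coords, as.vector(t(res$vnat)))
        keep <- c(keep, nm)
        perSample[[nm]] <- res$prov
      }
    }
    if (length(keep) < 3)
      stop("buildCorrespondenceSet: fewer than 3 samples survived registration")
    cs <- new("CorrespondenceSet", coords = coords, faces = faces(template),
              sampleIds = keep, regionLabels = templLabels,
              provenance = list(pass = pass, samples = perSample))
    if (pass < templateIterations) {
      aligned <- generalizedProcrustes(cs)
      model <- fitShapeModel(aligned)
      template <- instanceMesh(model) # the mean shape as the new template
    }
  }
  rejected <- names(perSample)[vapply(perSample, function(p)
    isTRUE(p$rejected), logical(1))]
  cs@provenance$rejected <- rejected
  cs@provenance$templateIndex <- templateIndex
  cs@provenance$templateIterations <- templateIterations
  cs
}

# i-th corresponded sample as a TriangleMesh
#' Extract one corresponded sample as a mesh
#' @param corr a [CorrespondenceSet-class].
#' @param i sample index or id.
#' @return a [TriangleMesh-class] with the template topology and labels.
#' @export
corrMesh <- function(corr, i) {
  if (is.character(i)) i <- match(i, corr@sampleIds)
  TriangleMesh(matrix(corr@coords[i, ], ncol = 3, byrow = TRUE),
               corr@faces, corr@regionLabels, validate = FALSE)
}
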