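# The statistical core: generalized Procrustes alignment of corresponded
# vertex sets, PCA modes of variation, instance generation, compactness and
# leave-one-out generalization.

# Kabsch rotation (+ optional scale) aligning X onto Y, both centered.
.kabsch <- function(X, Y, withScale = FALSE) {
  S <- crossprod(Y, X)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  s <- if (withScale) sum(sv$d * c(1, 1, d)) / sum(X^2) else 1
  list(R = R, s = s)
}

#' Generalized Procrustes alignment
#'
#' Iteratively aligns every corresponded sample to the evolving mean by
#' rotation and translation (and uniform scale only when
#' `removeScale = TRUE`). By default scale is retained, so size differences
#' remain in the data and PCA can recover scaling as a mode of variation.
#' All centroids end at the origin.
#'
#' @param corr a [CorrespondenceSet-class] with >= 3 samples.
#' @param removeScale also normalize size (default FALSE).
#' @param tol convergence threshold on the mean-shape change, mm.
#' @param maxIter iteration cap.
#' @return the aligned [CorrespondenceSet-class]; provenance gains
#'   `procrustes` diagnostics.
#' @export
generalizedProcrustes <- function(corr, removeScale = FALSE, tol = 1e-7,
                                  maxIter = 200) {
  K <- nrow(corr@coords)
  if (K < 3) stop("generalizedProcrustes: need at least 3 samples")
  configs <- lapply(seq_len(K), function(i)
    matrix(corr@coords[i, ], ncol = 3, byrow = TRUE))
  configs <- lapply(configs, function(X) sweep(X, 2, colMeans(X)))
  if (removeScale)
    configs <- lapply(configs, function(X) X / sqrt(sum(X^2)))
  mean0 <- configs[[1]]
  iters <- 0
  repeat {
    iters <- iters + 1
    configs <- lapply(configs, function(X) {
      k <- .kabsch(X, mean0, withScale = removeScale)
      k$s * X %*% t(k$R)
    })
    mean1 <- Reduce(`+`, configs) / K
    delta <- max(abs(mean1 - mean0))
    mean0 <- mean1
    if (delta < tol || iters >= maxIter) break
  }
  coords <- do.call(rbind, lapply(configs, function(X) as.vector(t(X))))
  out <- corr
  out@coords <- coords
  out@provenance$procrustes <- list(iterations = iters, removeScale = removeScale,
                                    converged = iters < maxIter)
  out
}

#' Fit a PCA shape model to an aligned correspondence set
#'
#' Mean = vertex-wise arithmetic mean; modes and variances from the
#' eigendecomposition of the sample covariance (divisor n - 1), computed on
#' the K x K Gram matrix since 3N >> K. At most n - 1 modes are retained
#' (numerically null directions are dropped). Each mode's sign is fixed so
#' that an increasing score increases centroid size, which orients the
#' scaling mode from small to large.
#'
#' @param aligned a Procrustes-aligned [CorrespondenceSet-class].
#' @return a [ShapeModel-class].
#' @export
fitShapeModel <- function(aligned) {
  X <- aligned@coords
  n <- nrow(X)
  if (n < 3) stop("fitShapeModel: need at least 3 samples")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  G <- tcrossprod(Xc) / (n - 1)
  e <- eigen(G, symmetric = TRUE)
  # drop numerically null directions: far below working precision they are
  # noise vectors that would not even come out orthonormal
  keep <- which(e$values > max(e$values, 0) * 1e-8 & e$values > 0)
  keep <- keep[seq_len(min(length(keep), n - 1))]
  if (length(keep) == 0) {
    modes <- matrix(numeric(0), nrow = ncol(X), ncol = 0)
    vars <- numeric(0)
  } else {
    vars <- e$values[keep]
    modes <- crossprod(Xc, e$vectors[, keep, drop = FALSE])
    modes <- sweep(modes, 2, sqrt(colSums(modes^2)), "/")
    # one Gram-Schmidt pass scrubs residual round-off in trailing modes
    modes <- qr.Q(qr(modes))
    # sign convention: +score grows centroid size
    for (k in seq_along(vars)) {
      d <- sum(modes[, k] * mu)
      if (abs(d) < 1e-8) d <- modes[which.max(abs(modes[, k])), k]
      if (d < 0) modes[, k] <- -modes[, k]
    }
  }
  new("ShapeModel", meanShape = as.double(mu), modes = modes,
      variances = as.double(vars), faces = aligned@faces,
      nSamples = as.integer(n), regionLabels = aligned@regionLabels,
      modeDescriptions = character(0))
}

#' Generate a shape-model instance
#'
#' `instanceScores` builds the vertex vector `mean + sum(score_k *
#' sqrt(variance_k) * mode_k)`; `instanceMesh` wraps it into a
#' [TriangleMesh-class] with the template topology and region labels.
#' Scores are SD multipliers: `c(2, 0, -1)` means +2 SD along mode 1 and
#' -1 SD along mode 3.
#'
#' @param model a [ShapeModel-class].
#' @param scores numeric vector of SD multipliers, one per leading mode
#'   (shorter vectors are zero-padded), or a named specification built by
#'   [modeRequest()].
#' @return `instanceMesh`: a [TriangleMesh-class]; `instanceScores`: the
#'   3N vertex vector.
#' @export
instanceScores <- function(model, scores = numeric(0)) {
  m <- nModes(model)
  if (length(scores) > m)
    stop("instance request references mode ", length(scores),
         " but the model has ", m, " modes")
  if (any(abs(scores) > 3))
    warning("instance outside +/-3 SD requested")
  v <- model@meanShape
  for (k in seq_along(scores)) {
    if (scores[k] != 0)
      v <- v + scores[k] * sqrt(model@variances[k]) * model@modes[, k]
  }
  v
}

#' @rdname instanceScores
#' @export
instanceMesh <- function(model, scores = numeric(0)) {
  v <- instanceScores(model, scores)
  TriangleMesh(matrix(v, ncol = 3, byrow = TRUE), model@faces,
               model@regionLabels, validate = FALSE)
}

#' @rdname instanceScores
#' @param mode 1-based mode index.
#' @param sd SD multiplier.
#' @export
modeRequest <- function(model, mode, sd) {
  if (mode > nModes(model)) stop("mode index ", mode, " exceeds ",
                                 nModes(model), " modes")
  scores <- numeric(mode)
  scores[mode] <- sd
  scores
}

#' Compactness: cumulative variance fractions and 95% mode selection
#'
#' @param model a [ShapeModel-class].
#' @return `cumulativeVariance`: non-decreasing fractions ending at 1;
#'   `selectModes`: the smallest mode count reaching `threshold`.
#' @export
cumulativeVariance <- function(model) {
  v <- model@variances
  if (!length(v)) return(numeric(0))
  cumsum(v) / sum(v)
}

#' @rdname cumulativeVariance
#' @param threshold cumulative-variance target (default 0.95).
#' @export
selectModes <- function(model, threshold = 0.95) {
  cv <- cumulativeVariance(model)
  if (!length(cv)) return(0L)
  as.integer(which(cv >= threshold - 1e-12)[1])
}

#' Leave-one-out generalization analysis
#'
#' Correspondence is established once across all samples (two template
#' passes by default); then for each fold the shape model is refit on the
#' remaining n - 1 corresponded samples, the left-out shape is
#' Procrustes-aligned (pose only) to the fold mean and projected onto the
#' first j modes for j = 0..m, and the reconstruction is scored against the
#' left-out original mesh. Two error matrices are returned: `surface` is the
#' symmetric mean surface distance to the original sample (the
#' part-comparison metric), `rmse` the vertex-space RMS error of the
#' corresponded shape, which is exactly non-increasing in j (nested
#' least-squares projections).
#'
#' @param samples list of >= 4 [TriangleMesh-class] objects.
#' @param corr optional precomputed [CorrespondenceSet-class] for `samples`.
#' @param templateIterations,epsCorr passed to [buildCorrespondenceSet()].
#' @param maxModes cap on the mode counts evaluated (default all).
#' @return list with matrices `surface` and `rmse` (fold x mode-count,
#'   columns j = 0..m), `meanPerModeCount`, `rmsPerModeCount` and `folds`.
#' @export
leaveOneOut <- function(samples, corr = NULL, templateIterations = 2,
                        epsCorr = 1.0, maxModes = NULL) {
  if (length(samples) < 4) stop("leaveOneOut: need at least 4 samples")
  if (is.null(corr))
    corr <- buildCorrespondenceSet(samples, templateIterations = templateIterations,
                                   epsCorr = epsCorr)
  if (is.null(names(samples)))
    names(samples) <- sprintf("sample%02d", seq_along(samples))
  ids <- sampleIds(corr)
  K <- length(ids)
  mMax <- K - 2 # per-fold model has K-1 samples, hence <= K-2 modes
  if (!is.null(maxModes)) mMax <- min(mMax, maxModes)
  surface <- matrix(NA_real_, K, mMax + 1,
                    dimnames = list(ids, paste0("m", 0:mMax)))
  rmse <- surface
  for (i in seq_len(K)) {
    foldCorr <- corr
    foldCorr@coords <- corr@coords[-i, , drop = FALSE]
    foldCorr@sampleIds <- ids[-i]
    aligned <- generalizedProcrustes(foldCorr)
    model <- fitShapeModel(aligned)
    # pose-align the left-out corresponded shape to the fold mean
    X0 <- matrix(corr@coords[i, ], ncol = 3, byrow = TRUE)
    cX0 <- colMeans(X0)
    X <- sweep(X0, 2, cX0)
    k <- .kabsch(X, matrix(model@meanShape, ncol = 3, byrow = TRUE))
    Xa <- X %*% t(k$R)
    x <- as.vector(t(Xa))
    centered <- x - model@meanShape
    coef <- crossprod(model@modes, centered)
    # score against the original mesh, mapped into the correspondence
    # frame with the pose of its stored registration (scale inverted, as
    # in the correspondence set itself)
    orig <- samples[[ids[i]]]
    tr <- corr@provenance$samples[[ids[i]]]$transform
    origC <- if (!is.null(tr)) {
      vv <- applyTransform(vertices(orig), tr) / tr@scale
      TriangleMesh(vv, faces(orig), validate = FALSE)
    } else orig
    for (j in 0:mMax) {
      jj <- min(j, nModes(model))
      recon <- model@meanShape
      if (jj > 0)
        recon <- recon + model@modes[, seq_len(jj), drop = FALSE] %*%
          coef[seq_len(jj)]
      rmse[i, j + 1] <- sqrt(mean((x - recon)^2) * 3)
      # back into the stored correspondence frame (undo the fold pose)
      rback <- sweep(matrix(recon, ncol = 3, byrow = TRUE) %*% k$R, 2, -cX0)
      rmesh <- TriangleMesh(rback, corr@faces, validate = FALSE)
      surface[i, j + 1] <- meanSurfaceDistance(rmesh, origC)
    }
  }
  list(surface = surface, rmse = rmse,
       meanPerModeCount = colMeans(surface, na.rm = TRUE),
       rmsPerModeCount = sqrt(colMeans(surface^2, na.rm = TRUE)),
       folds = ids)
}
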