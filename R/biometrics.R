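# Femoral and tibial biometric suites. Measurements are constructed from
# region labels alone (fitted spheres/axes and directional extremes), so
# they are rigid-motion invariant: the anatomical frame is derived from the
# bone itself, never from the scanner frame.

.regionVerts <- function(mesh, regions, name) {
  idx <- regions[[name]]
  if (is.null(idx) || !length(idx))
    stop("measure: missing or empty region '", name, "'")
  vertices(mesh)[idx, , drop = FALSE]
}

.centroid <- function(mesh, regions, name) {
  colMeans(.regionVerts(mesh, regions, name))
}

.biom <- function(bone, values, units, provenance) {
  new("BiometricSet", bone = bone, values = values, units = units,
      provenance = provenance)
}

#' Measure the femoral biometric suite
#'
#' Computes the ten standard femur measurements: full length (most proximal
#' point of the greater trochanter to the most distal point of the lateral
#' trochlear tubercle), bicondylar width, medial condylar width and depth,
#' best-fit radii of the medial condyle and femoral head, FMA angle
#' (mechanical vs anatomical axis, coronal plane), femoral neck angle (neck
#' axis vs distally directed anatomical axis), trochlear tubercle angle
#' (condylar center to tubercle sphere center vs anatomical axis) and
#' femoral version angle (neck axis vs transcondylar axis in the transverse
#' plane).
#'
#' Required regions: `greater_trochanter`, `lateral_trochlear_tubercle`,
#' `medial_trochlear_tubercle`, `medial_condyle`, `lateral_condyle`,
#' `femoral_head`, `femoral_neck`, `diaphysis`.
#'
#' @param mesh a [TriangleMesh-class] in left-limb convention.
#' @param regions region annotations; default `regionLabels(mesh)`.
#' @param frame optional [AnatomicalFrame-class]; derived from the regions
#'   when NULL.
#' @return a [BiometricSet-class].
#' @export
measureFemur <- function(mesh, regions = regionLabels(mesh), frame = NULL) {
  needed <- c("greater_trochanter", "lateral_trochlear_tubercle",
              "medial_trochlear_tubercle", "medial_condyle",
              "lateral_condyle", "femoral_head", "femoral_neck", "diaphysis")
  for (nm in needed)
    if (is.null(regions[[nm]]) || !length(regions[[nm]]))
      stop("measureFemur: missing region '", nm, "'")
  v <- vertices(mesh)
  prov <- list()
  sphM <- fitSphere(v[regions$medial_condyle, , drop = FALSE])
  sphL <- fitSphere(v[regions$lateral_condyle, , drop = FALSE])
  sphH <- fitSphere(v[regions$femoral_head, , drop = FALSE])
  sphT <- fitSphere(v[regions$medial_trochlear_tubercle, , drop = FALSE])
  prov$spheres <- list(medial_condyle = sphM, lateral_condyle = sphL,
                       femoral_head = sphH, medial_tubercle = sphT)
  condCenter <- (sphM$center + sphL$center) / 2
  transcondylar <- sphL$center - sphM$center # medial -> lateral
  ax <- fitAxisNormals(mesh, regions$diaphysis)
  pd <- ax$direction
  if (sum(pd * (condCenter - ax$point)) < 0) pd <- -pd # point distal
  if (is.null(frame))
    frame <- AnatomicalFrame(condCenter, PD = pd, ML = transcondylar)
  prov$frame <- frame
  prov$anatomicalAxis <- ax
  # length
  iTro <- extremeVertex(mesh, -frame@PD, regions$greater_trochanter)
  iTub <- extremeVertex(mesh, frame@PD, regions$lateral_trochlear_tubercle)
  len <- sqrt(sum((v[iTro, ] - v[iTub, ])^2))
  prov$length <- list(proximal = iTro, distal = iTub)
  # widths along the frame axes
  condAll <- c(regions$medial_condyle, regions$lateral_condyle)
  mlAll <- as.vector(v[condAll, , drop = FALSE] %*% frame@ML)
  bicond <- max(mlAll) - min(mlAll)
  # medial condylar width: most medial condyle point to the intercondylar
  # midline (the plane through the condylar center normal to ML); built
  # from fitted sphere centers rather than crease vertices for stability
  mlMed <- as.vector(v[regions$medial_condyle, , drop = FALSE] %*% frame@ML)
  widMed <- sum(condCenter * frame@ML) - min(mlMed)
  ccMed <- as.vector(v[regions$medial_condyle, , drop = FALSE] %*% frame@CrCd)
  depMed <- max(ccMed) - min(ccMed)
  # angles
  mech <- sphH$center - condCenter
  fma <- lineAngle(mech, frame@PD, planeNormal = frame@CrCd)
  neckAx <- fitAxisNormals(mesh, regions$femoral_neck,
                           orient = sphH$center - condCenter)
  prov$neckAxis <- neckAx
  neckAngle <- projectedAngle(neckAx$direction, frame@PD)
  version <- lineAngle(neckAx$direction, transcondylar,
                       planeNormal = frame@PD)
  tuberc <- lineAngle(sphT$center - condCenter, frame@PD)
  vals <- c(length = len, bicondylar_width = bicond,
            medial_condylar_width = widMed, medial_condylar_depth = depMed,
            medial_condylar_radius = sphM$radius,
            femoral_head_radius = sphH$radius,
            fma_angle = fma, neck_angle = neckAngle,
            tubercle_angle = tuberc, version_angle = version)
  units <- stats::setNames(c(rep("mm", 6), rep("deg", 4)), names(vals))
  .biom("femur", vals, units, prov)
}

#' Measure the tibial biometric suite
#'
#' Computes the seven standard tibia measurements: full length (most
#' proximal point of the medial intercondylar eminence, MICET, to the most
#' distal point of the distal ridge), bicondylar width (most medial to most
#' lateral plateau point), medial condylar width (most medial plateau point
#' to the MICET border found by the mean + 1 SD Gaussian-curvature rule),
#' medial condylar depth (most cranial to most caudal point of the medial
#' plateau), CTP angle (plateau joint line vs anatomical axis, coronal
#' plane) and the medial and lateral caudal tibial slope (CTS) angles
#' (plateau cranial-caudal line vs the perpendicular to the anatomical axis,
#' sagittal plane).
#'
#' Required regions: `micet`, `plateau_medial`, `plateau_lateral`,
#' `distal_ridge`, `diaphysis`.
#'
#' @inheritParams measureFemur
#' @param curvatureKSd threshold multiplier of the MICET border rule.
#' @return a [BiometricSet-class]. If the curvature border is empty the
#'   medial condylar width falls back to the full medial-region extent and
#'   `provenance(x)$micetBorder$fallback` is TRUE.
#' @export
measureTibia <- function(mesh, regions = regionLabels(mesh), frame = NULL,
                         curvatureKSd = 1) {
  needed <- c("micet", "plateau_medial", "plateau_lateral", "distal_ridge",
              "diaphysis")
  for (nm in needed)
    if (is.null(regions[[nm]]) || !length(regions[[nm]]))
      stop("measureTibia: missing region '", nm, "'")
  v <- vertices(mesh)
  prov <- list()
  ax <- fitAxisNormals(mesh, regions$diaphysis)
  pd <- ax$direction
  if (sum(pd * (colMeans(v[regions$distal_ridge, , drop = FALSE]) -
                ax$point)) < 0)
    pd <- -pd
  plateauIdx <- unique(c(regions$plateau_medial, regions$plateau_lateral,
                         regions$micet))
  plateau <- v[plateauIdx, , drop = FALSE]
  # ML direction: dominant in-plane spread of the plateau, pointing away
  # from the (medial) intercondylar eminence
  ev <- eigen(stats::cov(plateau), symmetric = TRUE)$vectors
  mlRaw <- ev[, 1] - sum(ev[, 1] * pd) * pd
  micetSide <- colMeans(v[regions$micet, , drop = FALSE]) - colMeans(plateau)
  if (sum(mlRaw * micetSide) > 0) mlRaw <- -mlRaw
  if (is.null(frame))
    frame <- AnatomicalFrame(colMeans(plateau), PD = pd, ML = mlRaw)
  prov$frame <- frame
  prov$anatomicalAxis <- ax
  # joint-line landmarks
  iMed <- plateauIdx[which.min(plateau %*% frame@ML)]
  iLat <- plateauIdx[which.max(plateau %*% frame@ML)]
  prov$jointLine <- c(medial = iMed, lateral = iLat)
  bicond <- sqrt(sum((v[iLat, ] - v[iMed, ])^2))
  ctp <- lineAngle(v[iLat, ] - v[iMed, ], frame@PD, planeNormal = frame@CrCd)
  # length
  iProx <- extremeVertex(mesh, -frame@PD, regions$micet)
  iDist <- extremeVertex(mesh, frame@PD, regions$distal_ridge)
  len <- sqrt(sum((v[iProx, ] - v[iDist, ])^2))
  prov$length <- list(proximal = iProx, distal = iDist)
  # caudal slopes per compartment + medial depth
  ctsOf <- function(regionName) {
    idx <- regions[[regionName]]
    iCr <- extremeVertex(mesh, -frame@CrCd, idx)
    iCa <- extremeVertex(mesh, frame@CrCd, idx)
    line <- v[iCa, ] - v[iCr, ]
    alpha <- lineAngle(line, frame@PD, planeNormal = frame@ML)
    list(cts = 90 - alpha, depth = sqrt(sum(line^2)),
         cranial = iCr, caudal = iCa)
  }
  med <- ctsOf("plateau_medial")
  lat <- ctsOf("plateau_lateral")
  prov$cts <- list(medial = med, lateral = lat)
  # MICET border by the curvature rule
  statRegion <- unique(c(regions$plateau_medial, regions$micet))
  border <- suppressWarnings(
    curvatureBorder(mesh, statRegion, kSd = curvatureKSd,
                    craniocaudal = frame@CrCd, surfaceNormal = -frame@PD))
  if (border$empty) {
    mlMed <- as.vector(v[regions$plateau_medial, , drop = FALSE] %*% frame@ML)
    widMed <- max(mlMed) - min(mlMed)
    border$fallback <- TRUE
    warning("measureTibia: empty curvature border; medial condylar width ",
            "falls back to the full medial-plateau extent")
  } else {
    border$fallback <- FALSE
    mlSel <- as.vector(v[border$vertices, , drop = FALSE] %*% frame@ML)
    widMed <- min(mlSel) - sum(v[iMed, ] * frame@ML)
  }
  prov$micetBorder <- border
  vals <- c(length = len, bicondylar_width = bicond,
            medial_condylar_width = widMed,
            medial_condylar_depth = med$depth,
            ctp_angle = ctp, cts_medial = med$cts, cts_lateral = lat$cts)
  units <- stats::setNames(c(rep("mm", 4), rep("deg", 3)), names(vals))
  .biom("tibia", vals, units, prov)
}

#' Mode-range summary over the canonical +/-3 SD instances
#'
#' Measures one biometric on the seven canonical instances of a mode
#' (-3..+3 SD) and summarizes the range the way the mode tables are read:
#' `percentIncrease = 100 * (v(+3SD) - v(-3SD)) / v(-3SD)` for length-type
#' biometrics and `rangeWidth = v(+3SD) - v(-3SD)`.
#'
#' @param model a [ShapeModel-class] whose template carries region labels.
#' @param modeIndex 1-based mode.
#' @param biometric biometric name (see [measureFemur()], [measureTibia()]).
#' @param measurer [measureFemur] or [measureTibia] (or any function mapping
#'   a mesh to a [BiometricSet-class]).
#' @return list of class "ModeRangeSummary" with `values` (named -3..+3),
#'   `percentIncrease` (NA for angles), `percentIncreaseRounded` and
#'   `rangeWidth`.
#' @export
modeRangeSummary <- function(model, modeIndex, biometric, measurer) {
  sds <- -3:3
  vals <- vapply(sds, function(k) {
    bs <- measurer(instanceMesh(model, modeRequest(model, modeIndex, k)))
    unname(biometricValues(bs)[biometric])
  }, numeric(1))
  names(vals) <- paste0(ifelse(sds > 0, "+", ""), sds, "SD")
  unit <- "mm"
  bs0 <- measurer(instanceMesh(model))
  unit <- unname(biometricUnits(bs0)[biometric])
  modeRangeStats(vals, unit = unit, biometric = biometric,
                 modeIndex = modeIndex)
}

#' @rdname modeRangeSummary
#' @param values numeric(7) biometric values at -3,-2,-1,0,+1,+2,+3 SD
#'   (e.g. a printed mode-table row).
#' @param unit "mm" (length-type: percent increase defined) or "deg".
#' @export
modeRangeStats <- function(values, unit = "mm", biometric = NA_character_,
                           modeIndex = NA_integer_) {
  stopifnot(length(values) == 7)
  lo <- values[1]
  hi <- values[7]
  pct <- if (identical(unit, "mm")) {
    if (lo <= 0) stop("percent increase needs a positive -3SD value")
    100 * (hi - lo) / lo
  } else NA_real_
  structure(list(biometric = biometric, modeIndex = modeIndex,
                 values = values, unit = unit,
                 percentIncrease = pct,
                 percentIncreaseRounded = if (is.na(pct)) NA_real_
                                          else round(pct),
                 rangeWidth = hi - lo),
            class = "ModeRangeSummary")
}

#' @export
print.ModeRangeSummary <- function(x, ...) {
  cat("ModeRangeSummary", if (!is.na(x$biometric)) paste0("(", x$biometric,
      ", mode ", x$modeIndex, ")"), "\n")
  print(round(x$values, 2))
  if (!is.na(x$percentIncrease))
    cat(sprintf("  increase -3SD -> +3SD: %.1f%% (~%d%%)\n",
                x$percentIncrease, x$percentIncreaseRounded))
  cat(sprintf("  range width: %.2f %s\n", x$rangeWidth, x$unit))
  invisible(x)
}

#' Valgus/varus convention for the coronal tibial plateau angle
#'
#' Positive values are valgus (joint line tilted so the lateral side is
#' distal), negative varus: `90 - ctpAngle` degrees.
#' @param ctpAngle CTP angle in degrees, in (0, 180).
#' @return signed degrees.
#' @export
valgusVarus <- function(ctpAngle) {
  stopifnot(ctpAngle > 0, ctpAngle < 180)
  90 - ctpAngle
}

#' Transfer region labels between meshes via the supporting surface face
#'
#' Each target vertex is projected onto the source surface and inherits a
#' region only when all three corners of its supporting source face carry
#' that region. This keeps fitted primitives clean: vertices projecting
#' onto boundary faces (partially labelled) stay unlabelled rather than
#' contaminating a sphere or axis fit.
#' The face rule is right for regions feeding sphere or axis fits; for
#' regions used only through a directional extreme (a landmark), the
#' nearest-vertex rule keeps isolated landmark vertices in play, so those
#' regions can be listed in `vertexRegions`.
#'
#' @param from labelled source [TriangleMesh-class].
#' @param to target [TriangleMesh-class].
#' @param maxDist optional rejection distance to the source surface, mm.
#' @param vertexRegions region names transferred by the nearest-vertex rule
#'   instead of the all-corners face rule.
#' @return `to` with transferred region labels.
#' @export
transferRegionLabels <- function(from, to, maxDist = Inf,
                                 vertexRegions = character(0)) {
  cp <- closestPointOnSurface(vertices(to), from)
  supp <- faces(from)[cp$face, , drop = FALSE]
  nn <- .cppNearestPoint(vertices(to), vertices(from))
  labels <- lapply(stats::setNames(nm = names(regionLabels(from))),
                   function(nm) {
    idx <- regionLabels(from)[[nm]]
    if (nm %in% vertexRegions) {
      sort(which(nn$index %in% idx & cp$distance <= maxDist))
    } else {
      inReg <- matrix(supp %in% idx, nrow(supp))
      sort(which(rowSums(inReg) == 3 & cp$distance <= maxDist))
    }
  })
  regionLabels(to) <- labels
  to
}
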