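#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib equiSSM, .registration = TRUE
NULL

#' TriangleMesh: a triangulated surface in millimetres
#'
#' The universal surface container of the package: an \code{n x 3} vertex
#' matrix (mm), an \code{f x 3} integer face matrix (1-based vertex indices,
#' counter-clockwise winding for outward normals), and an optional named list
#' of anatomical region labels, each an integer vector of vertex indices.
#'
#' @slot vertices numeric matrix, one vertex per row, columns x/y/z in mm.
#' @slot faces integer matrix, one triangle per row, 1-based vertex indices.
#' @slot regionLabels named list of integer vertex-index vectors, possibly
#'   empty, mapping anatomical region names to the vertices that carry them.
#'
#' @seealso [TriangleMesh()] for the validating constructor, [loadMesh()],
#'   [saveMesh()].
#' @export
setClass("TriangleMesh",
  representation(
    vertices = "matrix",
    faces = "matrix",
    regionLabels = "list"
  ),
  prototype(
    vertices = matrix(numeric(0), ncol = 3),
    faces = matrix(integer(0), ncol = 3),
    regionLabels = list()
  )
)

setValidity("TriangleMesh", function(object) {
  v <- object@vertices
  f <- object@faces
  msgs <- character(0)
  if (ncol(v) != 3) msgs <- c(msgs, "vertices must have 3 columns")
  if (ncol(f) != 3) msgs <- c(msgs, "faces must have 3 columns")
  if (nrow(f) > 0) {
    if (!is.numeric(f)) msgs <- c(msgs, "faces must be integer-valued")
    else {
      if (min(f) < 1 || max(f) > nrow(v))
        msgs <- c(msgs, "face indices out of vertex range")
      if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
        msgs <- c(msgs, "faces must not repeat a vertex")
    }
  }
  rl <- object@regionLabels
  if (length(rl)) {
    if (is.null(names(rl)) || any(!nzchar(names(rl))))
      msgs <- c(msgs, "regionLabels must be a named list")
    bad <- vapply(rl, function(idx) {
      length(idx) > 0 && (min(idx) < 1 || max(idx) > nrow(v))
    }, logical(1))
    if (any(bad))
      msgs <- c(msgs, paste("regionLabels reference invalid vertices:",
                            paste(names(rl)[bad], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' AnatomicalFrame: an orthonormal anatomical coordinate frame
#'
#' Houses the coronal/sagittal/transverse view constructions: an origin and
#' three pairwise-orthogonal unit axes in left-limb convention —
#' medial-to-lateral (ML), cranial-to-caudal (CrCd) and proximal-to-distal
#' (PD) — forming a right-handed triad in that order.
#'
#' @slot origin numeric(3), mm.
#' @slot ML,CrCd,PD numeric(3) unit vectors.
#' @export
setClass("AnatomicalFrame",
  representation(origin = "numeric", ML = "numeric", CrCd = "numeric",
                 PD = "numeric"))

setValidity("AnatomicalFrame", function(object) {
  ax <- list(ML = object@ML, CrCd = object@CrCd, PD = object@PD)
  msgs <- character(0)
  for (nm in names(ax)) {
    if (length(ax[[nm]]) != 3) msgs <- c(msgs, paste(nm, "must be length 3"))
    else if (abs(sqrt(sum(ax[[nm]]^2)) - 1) > 1e-9)
      msgs <- c(msgs, paste(nm, "must be a unit vector"))
  }
  if (!length(msgs)) {
    if (abs(sum(object@ML * object@CrCd)) > 1e-9 ||
        abs(sum(object@ML * object@PD)) > 1e-9 ||
        abs(sum(object@CrCd * object@PD)) > 1e-9)
      msgs <- c(msgs, "axes must be pairwise orthogonal")
    cr <- c(object@ML[2] * object@CrCd[3] - object@ML[3] * object@CrCd[2],
            object@ML[3] * object@CrCd[1] - object@ML[1] * object@CrCd[3],
            object@ML[1] * object@CrCd[2] - object@ML[2] * object@CrCd[1])
    if (sum(cr * object@PD) < 0)
      msgs <- c(msgs, "(ML, CrCd, PD) must be right-handed")
  }
  if (length(msgs)) msgs else TRUE
})

#' SimilarityTransform: rotation + translation + uniform scale
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(3), mm.
#' @slot scale positive scalar.
#' @export
setClass("SimilarityTransform",
  representation(rotation = "matrix", translation = "numeric",
                 scale = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0), scale = 1))

setValidity("SimilarityTransform", function(object) {
  R <- object@rotation
  msgs <- character(0)
  if (!all(dim(R) == c(3, 3))) msgs <- c(msgs, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
      msgs <- c(msgs, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-9)
      msgs <- c(msgs, "rotation determinant must be +1")
  }
  if (length(object@translation) != 3)
    msgs <- c(msgs, "translation must be length 3")
  if (length(object@scale) != 1 || object@scale <= 0)
    msgs <- c(msgs, "scale must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' CorrespondenceSet: corresponded vertex sets on one template topology
#'
#' K sample vertex arrays sharing a single template face list, the product of
#' similarity alignment plus non-rigid warping. Coordinates are stored as a
#' K x 3N matrix (rows are samples, vertex coordinates flattened x1 y1 z1
#' x2 ...), which is the layout PCA consumes directly.
#'
#' @slot coords numeric K x 3N matrix of corresponded vertex coordinates, mm.
#' @slot faces template face list shared by all samples.
#' @slot sampleIds character vector of K sample names.
#' @slot regionLabels template region labels, valid for every sample.
#' @slot provenance per-sample registration diagnostics (named list).
#' @export
setClass("CorrespondenceSet",
  representation(coords = "matrix", faces = "matrix",
                 sampleIds = "character", regionLabels = "list",
                 provenance = "list"))

setValidity("CorrespondenceSet", function(object) {
  msgs <- character(0)
  if (ncol(object@coords) %% 3 != 0)
    msgs <- c(msgs, "coords must have 3N columns")
  if (nrow(object@coords) != length(object@sampleIds))
    msgs <- c(msgs, "one sampleId per row of coords")
  n <- ncol(object@coords) / 3
  if (nrow(object@faces) > 0 && max(object@faces) > n)
    msgs <- c(msgs, "template faces reference out-of-range vertices")
  if (length(msgs)) msgs else TRUE
})

#' ShapeModel: a PCA statistical shape model
#'
#' Mean shape, orthonormal modes of variation and per-mode variances from a
#' Procrustes-aligned [CorrespondenceSet-class]. The number of modes is at
#' most n - 1 for n training samples.
#'
#' @slot meanShape numeric 3N vector, mm.
#' @slot modes 3N x m matrix of orthonormal mode vectors.
#' @slot variances numeric(m) eigenvalues, mm^2, non-increasing.
#' @slot faces template face list.
#' @slot nSamples number of training samples.
#' @slot regionLabels template region labels (propagated to instances).
#' @slot modeDescriptions optional character(m) annotations.
#' @export
setClass("ShapeModel",
  representation(meanShape = "numeric", modes = "matrix",
                 variances = "numeric", faces = "matrix",
                 nSamples = "integer", regionLabels = "list",
                 modeDescriptions = "character"))

setValidity("ShapeModel", function(object) {
  msgs <- character(0)
  m <- ncol(object@modes)
  if (length(object@variances) != m)
    msgs <- c(msgs, "one variance per mode")
  if (m > 0 && nrow(object@modes) != length(object@meanShape))
    msgs <- c(msgs, "modes and meanShape dimension mismatch")
  if (m > object@nSamples - 1)
    msgs <- c(msgs, "number of modes must not exceed n - 1")
  if (any(object@variances < -1e-12))
    msgs <- c(msgs, "variances must be non-negative")
  if (m > 1 && any(diff(object@variances) > 1e-9 * max(object@variances)))
    msgs <- c(msgs, "variances must be sorted non-increasing")
  if (m > 0) {
    G <- crossprod(object@modes)
    if (max(abs(G - diag(m))) > 1e-8)
      msgs <- c(msgs, "mode vectors must be orthonormal")
  }
  if (length(msgs)) msgs else TRUE
})

#' BiometricSet: named scalar bone measurements with provenance
#'
#' @slot bone "femur" or "tibia".
#' @slot values named numeric vector of measurements.
#' @slot units named character vector, "mm" or "deg", aligned with values.
#' @slot provenance named list of construction records (landmarks, fitted
#'   primitives, residuals, fallback flags).
#' @export
setClass("BiometricSet",
  representation(bone = "character", values = "numeric", units = "character",
                 provenance = "list"))

.FEMUR_BIOMETRICS <- c("length", "bicondylar_width", "medial_condylar_width",
  "medial_condylar_depth", "medial_condylar_radius", "femoral_head_radius",
  "fma_angle", "neck_angle", "tubercle_angle", "version_angle")

.TIBIA_BIOMETRICS <- c("length", "bicondylar_width", "medial_condylar_width",
  "medial_condylar_depth", "ctp_angle", "cts_medial", "cts_lateral")

setValidity("BiometricSet", function(object) {
  msgs <- character(0)
  if (!object@bone %in% c("femur", "tibia"))
    msgs <- c(msgs, "bone must be 'femur' or 'tibia'")
  expected <- if (identical(object@bone, "femur")) .FEMUR_BIOMETRICS
              else .TIBIA_BIOMETRICS
  if (!setequal(names(object@values), expected))
    msgs <- c(msgs, paste("values must contain exactly:",
                          paste(expected, collapse = ", ")))
  if (!identical(sort(names(object@units)), sort(names(object@values))))
    msgs <- c(msgs, "units must align with values")
  ok <- is.finite(object@values)
  isdeg <- object@units[names(object@values)] == "deg"
  if (any(object@values[ok & !isdeg] <= 0))
    msgs <- c(msgs, "lengths must be positive")
  if (any(object@values[ok & isdeg] < 0 | object@values[ok & isdeg] >= 180))
    msgs <- c(msgs, "angles must lie in [0, 180)")
  if (length(msgs)) msgs else TRUE
})
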