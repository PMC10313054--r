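# Generics and accessors. Slot access from user code goes through these.

#' @rdname TriangleMesh-class
#' @param object,x an object.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname TriangleMesh-class
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname TriangleMesh-class
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))
#' @rdname TriangleMesh-class
#' @param value replacement value.
#' @export
setGeneric("regionLabels<-",
           function(x, value) standardGeneric("regionLabels<-"))
#' @rdname TriangleMesh-class
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname TriangleMesh-class
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))

#' @rdname CorrespondenceSet-class
#' @param x an object.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname CorrespondenceSet-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname CorrespondenceSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ShapeModel-class
#' @param x an object.
#' @export
setGeneric("meanShape", function(x) standardGeneric("meanShape"))
#' @rdname ShapeModel-class
#' @export
setGeneric("shapeModes", function(x) standardGeneric("shapeModes"))
#' @rdname ShapeModel-class
#' @export
setGeneric("modeVariances", function(x) standardGeneric("modeVariances"))
#' @rdname ShapeModel-class
#' @export
setGeneric("nModes", function(x) standardGeneric("nModes"))

#' @rdname BiometricSet-class
#' @param x an object.
#' @export
setGeneric("biometricValues", function(x) standardGeneric("biometricValues"))
#' @rdname BiometricSet-class
#' @export
setGeneric("biometricUnits", function(x) standardGeneric("biometricUnits"))

#' @rdname TriangleMesh-class
#' @export
setMethod("vertices", "TriangleMesh", function(x) x@vertices)
#' @rdname TriangleMesh-class
#' @export
setMethod("faces", "TriangleMesh", function(x) x@faces)
#' @rdname TriangleMesh-class
#' @export
setMethod("regionLabels", "TriangleMesh", function(x) x@regionLabels)
#' @rdname TriangleMesh-class
#' @export
setReplaceMethod("regionLabels", "TriangleMesh", function(x, value) {
  x@regionLabels <- value
  validObject(x)
  x
})
#' @rdname TriangleMesh-class
#' @export
setMethod("nVertices", "TriangleMesh", function(x) nrow(x@vertices))
#' @rdname TriangleMesh-class
#' @export
setMethod("nFaces", "TriangleMesh", function(x) nrow(x@faces))

#' @rdname CorrespondenceSet-class
#' @export
setMethod("faces", "CorrespondenceSet", function(x) x@faces)
#' @rdname CorrespondenceSet-class
#' @export
setMethod("regionLabels", "CorrespondenceSet", function(x) x@regionLabels)
#' @rdname CorrespondenceSet-class
#' @export
setMethod("sampleIds", "CorrespondenceSet", function(x) x@sampleIds)
#' @rdname CorrespondenceSet-class
#' @export
setMethod("nSamples", "CorrespondenceSet", function(x) nrow(x@coords))
#' @rdname CorrespondenceSet-class
#' @export
setMethod("nVertices", "CorrespondenceSet", function(x) ncol(x@coords) / 3)
#' @rdname CorrespondenceSet-class
#' @export
setMethod("provenance", "CorrespondenceSet", function(x) x@provenance)

#' @rdname ShapeModel-class
#' @export
setMethod("meanShape", "ShapeModel", function(x) x@meanShape)
#' @rdname ShapeModel-class
#' @export
setMethod("shapeModes", "ShapeModel", function(x) x@modes)
#' @rdname ShapeModel-class
#' @export
setMethod("modeVariances", "ShapeModel", function(x) x@variances)
#' @rdname ShapeModel-class
#' @export
setMethod("nModes", "ShapeModel", function(x) ncol(x@modes))
#' @rdname ShapeModel-class
#' @export
setMethod("nSamples", "ShapeModel", function(x) as.integer(x@nSamples))
#' @rdname ShapeModel-class
#' @export
setMethod("faces", "ShapeModel", function(x) x@faces)
#' @rdname ShapeModel-class
#' @export
setMethod("regionLabels", "ShapeModel", function(x) x@regionLabels)
#' @rdname ShapeModel-class
#' @export
setMethod("nVertices", "ShapeModel", function(x) length(x@meanShape) / 3)

#' @rdname BiometricSet-class
#' @export
setMethod("biometricValues", "BiometricSet", function(x) x@values)
#' @rdname BiometricSet-class
#' @export
setMethod("biometricUnits", "BiometricSet", function(x) x@units)
#' @rdname BiometricSet-class
#' @export
setMethod("provenance", "BiometricSet", function(x) x@provenance)

setMethod("show", "TriangleMesh", function(object) {
  bb <- if (nrow(object@vertices)) {
    rng <- apply(object@vertices, 2, range)
    paste0(sprintf("%.1f", rng[2, ] - rng[1, ]), collapse = " x ")
  } else "empty"
  cat("TriangleMesh:", nrow(object@vertices), "vertices,",
      nrow(object@faces), "faces\n")
  cat("  bounding box (mm):", bb, "\n")
  if (length(object@regionLabels))
    cat("  regions:", paste(names(object@regionLabels), collapse = ", "), "\n")
})

setMethod("show", "CorrespondenceSet", function(object) {
  cat("CorrespondenceSet:", nrow(object@coords), "samples x",
      ncol(object@coords) / 3, "corresponded vertices\n")
  cat("  ids:", paste(utils::head(object@sampleIds, 5), collapse = ", "),
      if (length(object@sampleIds) > 5) "..." else "", "\n")
})

setMethod("show", "ShapeModel", function(object) {
  cat("ShapeModel:", ncol(object@modes), "modes from", object@nSamples,
      "samples,", length(object@meanShape) / 3, "vertices\n")
  if (length(object@variances)) {
    cv <- cumsum(object@variances) / sum(object@variances)
    cat("  mode-1 variance fraction:", sprintf("%.3f", cv[1]), "\n")
  }
})

setMethod("show", "BiometricSet", function(object) {
  cat("BiometricSet (", object@bone, "):\n", sep = "")
  for (nm in names(object@values))
    cat(sprintf("  %-24s %8.2f %s\n", nm, object@values[nm],
                object@units[nm]))
})

setMethod("show", "SimilarityTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("SimilarityTransform: scale %.4f, rotation %.2f deg, |t| %.2f mm\n",
              object@scale, ang, sqrt(sum(object@translation^2))))
})

setMethod("show", "AnatomicalFrame", function(object) {
  cat("AnatomicalFrame at (", paste(sprintf("%.1f", object@origin),
      collapse = ", "), ") mm\n", sep = "")
})
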