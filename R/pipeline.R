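# End-to-end pipeline and plain-text archives for the model objects.

#' Write / read a ShapeModel archive
#'
#' Structured text archive: a single JSON file holding the mean, modes,
#' variances, faces, region labels and metadata.
#' @param model a [ShapeModel-class].
#' @param path output path (".json" recommended).
#' @return `path` / the restored [ShapeModel-class].
#' @export
writeShapeModel <- function(model, path) {
  obj <- list(meanShape = model@meanShape,
              modes = model@modes,
              variances = model@variances,
              faces = model@faces,
              nSamples = model@nSamples,
              regionLabels = model@regionLabels,
              modeDescriptions = model@modeDescriptions)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeShapeModel
#' @export
readShapeModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  modes <- obj$modes
  if (is.null(dim(modes)))
    modes <- matrix(unlist(modes), nrow = length(obj$meanShape))
  faces <- matrix(as.integer(obj$faces), ncol = 3)
  labels <- lapply(obj$regionLabels, as.integer)
  new("ShapeModel", meanShape = as.double(obj$meanShape),
      modes = as.matrix(modes), variances = as.double(obj$variances),
      faces = faces, nSamples = as.integer(obj$nSamples),
      regionLabels = if (length(labels)) labels else list(),
      modeDescriptions = as.character(obj$modeDescriptions))
}

#' Write / read a CorrespondenceSet archive (JSON)
#' @param corr a [CorrespondenceSet-class].
#' @param path output path.
#' @return `path` / the restored [CorrespondenceSet-class].
#' @export
writeCorrespondenceSet <- function(corr, path) {
  obj <- list(coords = corr@coords, faces = corr@faces,
              sampleIds = corr@sampleIds, regionLabels = corr@regionLabels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname writeCorrespondenceSet
#' @export
readCorrespondenceSet <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  labels <- lapply(obj$regionLabels, as.integer)
  new("CorrespondenceSet", coords = as.matrix(obj$coords),
      faces = matrix(as.integer(obj$faces), ncol = 3),
      sampleIds = as.character(obj$sampleIds),
      regionLabels = if (length(labels)) labels else list(),
      provenance = list(restored = TRUE))
}

#' Run the full shape-modeling pipeline
#'
#' Correspondence (two template passes by default), generalized Procrustes,
#' PCA, compactness, optional leave-one-out, mode-range tables and the
#' mode-biometric correlation experiment; artifacts and a MANIFEST are
#' written to `outDir` when given.
#'
#' @param meshes named list of [TriangleMesh-class] bones (already in
#'   left-limb convention); the first labelled mesh supplies template
#'   region labels.
#' @param bone "femur" or "tibia" (selects the measurer).
#' @param outDir optional output directory.
#' @param seed global seed; stage seeds are derived from it.
#' @param templateIterations,epsCorr passed to [buildCorrespondenceSet()].
#' @param removeScale passed to [generalizedProcrustes()].
#' @param doLoo run the leave-one-out analysis (slowest stage).
#' @param nCorrelationInstances instances for [correlationExperiment()]
#'   (0 skips it).
#' @param modeTableModes modes summarized in the mode-range tables; default
#'   the 95% compactness selection.
#' @return list with `correspondence`, `model`, `cumulativeVariance`,
#'   `selectedModes`, `loo`, `correlations`, `modeTables`, `config`.
#' @export
runPipeline <- function(meshes, bone = c("femur", "tibia"), outDir = NULL,
                        seed = 1, templateIterations = 2, epsCorr = 1.0,
                        removeScale = FALSE, doLoo = FALSE,
                        nCorrelationInstances = 100,
                        modeTableModes = NULL) {
  bone <- match.arg(bone)
  if (length(meshes) < 3) stop("runPipeline: need at least 3 meshes")
  measurer <- if (bone == "femur") measureFemur else measureTibia
  config <- list(bone = bone, seed = seed,
                 templateIterations = templateIterations, epsCorr = epsCorr,
                 removeScale = removeScale, doLoo = doLoo,
                 nCorrelationInstances = nCorrelationInstances)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  corr <- buildCorrespondenceSet(meshes,
                                 templateIterations = templateIterations,
                                 epsCorr = epsCorr)
  aligned <- generalizedProcrustes(corr, removeScale = removeScale)
  model <- fitShapeModel(aligned)
  cv <- cumulativeVariance(model)
  nSel <- selectModes(model)
  loo <- NULL
  if (doLoo)
    loo <- leaveOneOut(meshes, corr = corr)
  correlations <- NULL
  if (nCorrelationInstances > 0 && length(regionLabels(model)))
    correlations <- correlationExperiment(model,
                       modes = min(nSel, nModes(model)),
                       nInstances = nCorrelationInstances,
                       measurer = measurer, seed = seed + 1)
  modeTables <- list()
  if (length(regionLabels(model))) {
    mt <- if (is.null(modeTableModes)) seq_len(min(nSel, nModes(model)))
          else modeTableModes
    bios <- names(biometricValues(measurer(instanceMesh(model))))
    for (k in mt) {
      tab <- lapply(bios, function(b)
        tryCatch(modeRangeSummary(model, k, b, measurer),
                 error = function(e) NULL))
      names(tab) <- bios
      modeTables[[paste0("mode", k)]] <- tab[!vapply(tab, is.null,
                                                     logical(1))]
    }
  }
  out <- list(correspondence = corr, model = model, cumulativeVariance = cv,
              selectedModes = nSel, loo = loo, correlations = correlations,
              modeTables = modeTables, config = config)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeShapeModel(model, file.path(outDir, "model.json"))
    writeCorrespondenceSet(corr, file.path(outDir, "correspondence.json"))
    utils::write.csv(data.frame(mode = seq_along(cv),
                                cumulativeVariance = cv),
                     file.path(outDir, "compactness.csv"), row.names = FALSE)
    if (!is.null(loo)) {
      utils::write.csv(as.data.frame(loo$surface),
                       file.path(outDir, "loo_surface.csv"))
      utils::write.csv(as.data.frame(loo$rmse),
                       file.path(outDir, "loo_rmse.csv"))
    }
    if (!is.null(correlations))
      utils::write.csv(correlations, file.path(outDir, "correlations.csv"),
                       row.names = FALSE)
    for (nm in names(modeTables)) {
      rows <- do.call(rbind, lapply(modeTables[[nm]], function(srm)
        data.frame(biometric = srm$biometric, unit = srm$unit,
                   t(srm$values), percentIncrease = srm$percentIncrease,
                   rangeWidth = srm$rangeWidth, check.names = FALSE)))
      utils::write.csv(rows, file.path(outDir, paste0(nm, "_table.csv")),
                       row.names = FALSE)
    }
    manifest <- list(config = config, nSamples = length(meshes),
                     sampleIds = names(meshes),
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     selectedModes = nSel,
                     packageVersion = as.character(
                       utils::packageVersion("equiSSM")))
    jsonlite::write_json(manifest, file.path(outDir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
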