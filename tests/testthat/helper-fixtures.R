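# Shared fixtures, built lazily and cached for the session. All synthetic
# geometry is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

unitCubeMesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
             c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
             c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8))
  TriangleMesh(v, f)
}

coarseFemur <- function(...) {
  makeBone(SyntheticBoneParams("femur", meshResolution = 8, ...))
}

coarseTibia <- function(...) {
  makeBone(SyntheticBoneParams("tibia", meshResolution = 8, ...))
}

refFemur <- function() fixture("refFemur", coarseFemur)
refTibia <- function() fixture("refTibia", coarseTibia)

# 15-bone scale-dominant femur study population with its correspondence
# set; shared by the scaling-dominance and leave-one-out analyses
femurStudy <- function() {
  fixture("femurStudy", function() {
    pop <- samplePopulation(15, "femur", spec = list(meshResolution = 8),
                            seed = 101)
    meshes <- lapply(pop, `[[`, "mesh")
    set.seed(101)
    corr <- buildCorrespondenceSet(meshes, templateIterations = 2)
    model <- fitShapeModel(generalizedProcrustes(corr))
    list(pop = pop, meshes = meshes, corr = corr, model = model)
  })
}

# six posed copies of one femur at graded scales; the canonical
# scale-only shape model
scaleOnlyStudy <- function() {
  fixture("scaleOnlyModel", function() {
    scales <- c(0.9, 0.95, 1, 1.05, 1.1, 1.15)
    meshes <- lapply(scales, function(s)
      makeBone(SyntheticBoneParams("femur", scale = s,
                                   meshResolution = 8))$mesh)
    names(meshes) <- sprintf("s%d", seq_along(meshes))
    set.seed(55)
    corr <- buildCorrespondenceSet(meshes, templateIterations = 1)
    list(scales = scales, meshes = meshes, corr = corr,
         model = fitShapeModel(generalizedProcrustes(corr)))
  })
}

rotationMatrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
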