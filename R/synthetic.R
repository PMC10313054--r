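# Parametric synthetic bones. The generator builds stylized femur-like and
# tibia-like closed meshes from analytic primitives (shaft tube, head and
# condylar spheres, neck cylinder, tilted plateau facets, a raised
# intercondylar mesa) so that every biometric construction has an exactly
# known answer. Key landmark vertices are snapped onto their analytic
# positions and region labels are assigned from the construction itself.
# The bones are deliberately stylized, not anatomically faithful: their
# purpose is ground truth for the measurement and modeling pipeline.

# ---- small geometry helpers -------------------------------------------------

.unit <- function(v) v / sqrt(sum(v^2))

# rotation taking unit vector a to unit vector b (Rodrigues)
.rotBetween <- function(a, b) {
  a <- .unit(a); b <- .unit(b)
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2))
  c0 <- sum(a * b)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    # opposite: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- .unit(p - sum(p * a) * a)
    K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - c0) / s^2)
}

# largest ray parameter t >= 0 with |o + t d - c| = r over a list of spheres
.rayExitSpheres <- function(o, d, centers, r) {
  best <- NA_real_
  for (i in seq_len(nrow(centers))) {
    oc <- o - centers[i, ]
    b <- sum(d * oc)
    disc <- b^2 - (sum(oc^2) - r^2)
    if (disc < 0) next
    t <- -b + sqrt(disc)
    if (is.na(best) || t > best) best <- t
  }
  best
}

# closed tube from a bottom apex, a list of rings (equal vertex count,
# consistently ordered) and a top apex; winding fixed to outward normals
.ringStack <- function(rings, bottomApex, topApex) {
  np <- nrow(rings[[1]])
  nr <- length(rings)
  v <- do.call(rbind, rings)
  ringIdx <- function(r) (r - 1) * np + seq_len(np)
  f <- NULL
  for (r in seq_len(nr - 1)) {
    a <- ringIdx(r)
    b <- ringIdx(r + 1)
    j2 <- c(seq_len(np)[-1], 1)
    f <- rbind(f,
               cbind(a, a[j2], b[j2]),
               cbind(a, b[j2], b))
  }
  v <- rbind(v, bottomApex, topApex)
  bi <- nrow(v) - 1
  ti <- nrow(v)
  a <- ringIdx(1)
  j2 <- c(seq_len(np)[-1], 1)
  f <- rbind(f, cbind(bi, a[j2], a))
  a <- ringIdx(nr)
  f <- rbind(f, cbind(ti, a, a[j2]))
  mesh <- TriangleMesh(v, f, validate = FALSE)
  if (meshVolume(mesh) < 0)
    mesh <- TriangleMesh(v, f[, c(1, 3, 2)], validate = FALSE)
  mesh
}

# move the region vertex nearest `target` exactly onto it
.snapVertex <- function(v, candidates, target) {
  d2 <- rowSums(sweep(v[candidates, , drop = FALSE], 2, target)^2)
  idx <- candidates[which.min(d2)]
  v[idx, ] <- target
  list(v = v, index = idx)
}

.smoothstep <- function(x) {
  x <- pmin(1, pmax(0, x))
  x * x * (3 - 2 * x)
}

#' Icosphere fixture
#'
#' A geodesic sphere from recursive icosahedron subdivision, projected onto
#' the sphere; the standard closed genus-0 test fixture.
#' @param radius sphere radius, mm.
#' @param subdivisions subdivision levels (0 = icosahedron).
#' @param center numeric(3) center.
#' @return a closed [TriangleMesh-class].
#' @export
icoSphere <- function(radius = 1, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nf <- nrow(f)
    mid <- new.env()
    getMid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(mid[[key]])) return(mid[[key]])
      m <- .unit(v[i, ] + v[j, ])
      v <<- rbind(v, m)
      mid[[key]] <- nrow(v)
      nrow(v)
    }
    f2 <- matrix(0L, nf * 4, 3)
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; c <- f[k, 3]
      ab <- getMid(a, b); bc <- getMid(b, c); ca <- getMid(c, a)
      f2[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(c, ca, bc), c(ab, bc, ca))
    }
    f <- f2
  }
  TriangleMesh(sweep(v * radius, 2, -center), f, validate = FALSE)
}

# ---- parameters -------------------------------------------------------------

#' Parameters of a synthetic bone
#'
#' Angles are in degrees; `scale` multiplies every linear dimension of the
#' reference bone. Reference femur: neck angle 157.3, FMA 6.7, version 43.5,
#' trochlear-tubercle angle 15.3, head radius 36.1 mm, condylar radius
#' 36 mm. Reference tibia: coronal plateau tilt 1.1 (CTP 88.9), medial
#' caudal slope 9.6, lateral caudal slope 17.6, plateau width 118 mm.
#'
#' @param bone "femur" or "tibia".
#' @param scale uniform scale in [0.5, 2].
#' @param neckAngle,versionAngle,fmaAngle,tubercleAngle femur angles, deg.
#' @param headRadius,condylarRadius femur sphere radii at scale 1, mm.
#' @param ctpTilt coronal plateau tilt (90 - CTP angle), deg.
#' @param ctsMedial,ctsLateral caudal tibial slopes, deg.
#' @param plateauWidth tibial bicondylar half-axis x 2 at scale 1, mm.
#' @param meshResolution target edge length, mm (at scale 1).
#' @param allowInvertedSlopes permit ctsLateral < ctsMedial (default FALSE:
#'   the lateral slope is expected to exceed the medial).
#' @return validated parameter list of class "SyntheticBoneParams".
#' @export
SyntheticBoneParams <- function(bone = c("femur", "tibia"), scale = 1,
    neckAngle = 157.3, versionAngle = 43.5, fmaAngle = 6.7,
    tubercleAngle = 15.3, headRadius = 36.1, condylarRadius = 36,
    ctpTilt = 1.1, ctsMedial = 9.6, ctsLateral = 17.6, plateauWidth = 118,
    meshResolution = if (bone[1] == "femur") 6 else 5,
    allowInvertedSlopes = FALSE) {
  bone <- match.arg(bone)
  stopifnot(scale >= 0.5, scale <= 2, meshResolution > 0)
  if (bone == "femur") {
    stopifnot(neckAngle > 120, neckAngle < 180,
              versionAngle > 0, versionAngle < 90,
              fmaAngle >= 0, fmaAngle < 30,
              tubercleAngle >= 12, tubercleAngle <= 30,
              headRadius > 10, condylarRadius > 10)
  } else {
    stopifnot(abs(ctpTilt) < 15, ctsMedial >= 0, ctsMedial < 35,
              ctsLateral >= 0, ctsLateral < 35, plateauWidth > 40)
    if (!allowInvertedSlopes && ctsLateral < ctsMedial)
      stop("ctsLateral < ctsMedial; the lateral slope is expected to be ",
           "larger (set allowInvertedSlopes = TRUE to override)")
  }
  structure(list(bone = bone, scale = scale, neckAngle = neckAngle,
                 versionAngle = versionAngle, fmaAngle = fmaAngle,
                 tubercleAngle = tubercleAngle, headRadius = headRadius,
                 condylarRadius = condylarRadius, ctpTilt = ctpTilt,
                 ctsMedial = ctsMedial, ctsLateral = ctsLateral,
                 plateauWidth = plateauWidth,
                 meshResolution = meshResolution),
            class = "SyntheticBoneParams")
}

# ---- femur ------------------------------------------------------------------

.makeFemur <- function(p) {
  s <- p$scale
  res <- p$meshResolution # sampling density in reference units
  deg <- pi / 180
  # reference-frame layout (left limb): +x lateral, +y caudal, +z proximal
  rc <- p$condylarRadius
  rh <- p$headRadius
  Wbc <- 106.7
  dc <- Wbc / 2 - rc
  if (dc <= 2) stop("condylarRadius too large for the bicondylar width")
  yc <- 8
  C <- c(0, yc, 0) # condylar center, also the ray origin for the distal cap
  cm <- c(-dc, yc, 0)
  cl <- c(dc, yc, 0)
  rs <- 22 # shaft radius
  zFlareTop <- 60
  zWallTop <- 260
  # mechanical axis: head center placed at the FMA angle in the coronal plane
  f <- p$fmaAngle * deg
  lm <- 360
  H <- C + lm * c(-sin(f), 0, cos(f))
  # neck axis from neck and version angles
  e <- (180 - p$neckAngle) * deg
  vv <- p$versionAngle * deg
  nax <- c(-sin(e) * cos(vv), sin(e) * sin(vv), cos(e))
  ln <- 95
  rn <- 15
  B <- H - ln * nax
  dJ <- sqrt(rh^2 - rn^2) # neck-sphere junction distance from head center
  # trochlear tubercles on the tubercle-angle cone from the condylar
  # center; the radial offset from the shaft axis is fixed so the spheres
  # protrude and expose their distal poles (smooth length landmarks)
  at <- p$tubercleAngle * deg
  gam <- 35 * deg
  # offset along the cone chosen so the centers sit 28 mm from the shaft
  # axis: the spheres protrude beyond the wall and expose their poles
  ot <- 8 * cos(gam) + sqrt((8 * cos(gam))^2 + 28^2 - 64)
  lt <- ot / sin(at)
  rt <- 13
  um <- c(-sin(at) * sin(gam), -sin(at) * cos(gam), cos(at))
  ul <- c(sin(at) * sin(gam), -sin(at) * cos(gam), cos(at))
  Tm <- C + lt * um
  Tl <- C + lt * ul
  # greater trochanter: a lateral sphere bump high on the wall whose
  # exposed proximal pole is the length landmark
  Ttro <- c(26, 0, 235)
  rtro <- 16

  np <- max(16, 4 * ceiling(2 * pi * rs / res / 4))
  phis <- 2 * pi * (seq_len(np) - 1) / np
  cph <- cos(phis); sph <- sin(phis)
  centers2 <- rbind(cm, cl)

  rings <- list()
  ringTag <- character(0)
  ringZ <- numeric(0)
  addRing <- function(ring, tag, z) {
    rings[[length(rings) + 1]] <<- ring
    ringTag <<- c(ringTag, tag)
    ringZ <<- c(ringZ, z)
  }
  # distal condylar cap: rays from C onto the union of the condylar spheres
  capArc <- (pi / 2) * (rc + dc)
  nCap <- max(5, ceiling(capArc / res))
  betas <- seq(pi - pi / nCap / 2, pi / 2, length.out = nCap)
  for (b in betas) {
    d <- cbind(sin(b) * cph, sin(b) * sph, cos(b))
    t <- vapply(seq_len(np), function(j)
      .rayExitSpheres(C, d[j, ], centers2, rc), numeric(1))
    addRing(sweep(d * t, 2, -C), "condyle", NA)
  }
  # outline radius at the equator, reused by the flare blend
  outl <- vapply(seq_len(np), function(j)
    .rayExitSpheres(C, c(cph[j], sph[j], 0), centers2, rc), numeric(1))
  # flare: elliptical outline relaxing to the circular shaft
  nFl <- max(3, ceiling(zFlareTop / res))
  for (z in seq(zFlareTop / nFl, zFlareTop, length.out = nFl)) {
    w <- .smoothstep(z / zFlareTop)
    rad <- (1 - w) * outl + w * rs
    ctr <- c(0, yc * (1 - w), 0)
    addRing(cbind(ctr[1] + rad * cph, ctr[2] + rad * sph, z), "flare", z)
  }
  # shaft wall
  nW <- ceiling((zWallTop - zFlareTop) / res)
  for (z in seq(zFlareTop + (zWallTop - zFlareTop) / nW, zWallTop,
                length.out = nW)) {
    addRing(cbind(rs * cph, rs * sph, z), "wall", z)
  }
  # transition to the neck
  Rzn <- .rotBetween(c(0, 0, 1), nax)
  ang <- acos(pmin(1, sum(nax * c(0, 0, 1))))
  axK <- .unit(c(-nax[2], nax[1], 0))
  slerp <- function(t) {
    th <- t * ang
    K <- matrix(c(0, axK[3], -axK[2], -axK[3], 0, axK[1],
                  axK[2], -axK[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  S1 <- c(0, 0, zWallTop)
  nT <- 4
  for (k in seq_len(nT)) {
    t <- k / (nT + 1)
    ctr <- (1 - t) * S1 + t * B
    Rf <- slerp(t)
    rad <- rs + (rn - rs) * .smoothstep(t)
    e1 <- Rf %*% c(1, 0, 0); e2 <- Rf %*% c(0, 1, 0)
    addRing(t(ctr + rad * (outer(as.vector(e1), cph) +
                           outer(as.vector(e2), sph))), "transition", NA)
  }
  # neck cylinder
  e1 <- Rzn %*% c(1, 0, 0); e2 <- Rzn %*% c(0, 1, 0)
  neckSpan <- ln - dJ - 4
  nN <- max(8, ceiling(neckSpan / res))
  neckU <- seq(2, neckSpan, length.out = nN)
  for (u in neckU) {
    ctr <- B + u * nax
    addRing(t(ctr + rn * (outer(as.vector(e1), cph) +
                          outer(as.vector(e2), sph))), "neck", u)
  }
  # femoral head: sphere bands from the neck junction to near the apex
  thJ <- pi - asin(rn / rh)
  nH <- max(8, ceiling(rh * thJ / res))
  thetas <- seq(thJ, 0.12, length.out = nH)
  for (th in thetas) {
    ctr <- H + rh * cos(th) * nax
    rad <- rh * sin(th)
    addRing(t(ctr + rad * (outer(as.vector(e1), cph) +
                           outer(as.vector(e2), sph))), "head", th)
  }
  bottomApex <- C + .rayExitSpheres(C, c(0, 0, -1), centers2, rc) * c(0, 0, -1)
  topApex <- H + rh * nax

  # assemble, then sculpt the wall: trochlear tubercles (sphere union) and
  # the greater-trochanter horn (vertical displacement)
  mesh <- .ringStack(rings, bottomApex, topApex)
  v <- vertices(mesh)
  vphi <- c(rep(phis, times = length(rings)), 0, 0)
  vtag <- c(rep(ringTag, each = np), "apexB", "apexT")
  vz0 <- v[, 3]
  bumpLab <- list(medial = integer(0), lateral = integer(0),
                  trochanter = integer(0))
  bumpSpheres <- list(medial = list(c = Tm, r = rt),
                      lateral = list(c = Tl, r = rt),
                      trochanter = list(c = Ttro, r = rtro))
  wallish <- which(vtag %in% c("flare", "wall"))
  for (side in names(bumpSpheres)) {
    Tc <- bumpSpheres[[side]]$c
    rb <- bumpSpheres[[side]]$r
    onSphere <- integer(0)
    for (i in wallish) {
      z <- v[i, 3]
      if (abs(z - Tc[3]) >= rb) next
      o <- c(0, 0, z) # ray origin on the shaft axis
      dirr <- c(cos(vphi[i]), sin(vphi[i]), 0)
      tex <- .rayExitSpheres(o, dirr, matrix(Tc, 1), rb)
      if (is.na(tex)) next
      cur <- sqrt(sum((v[i, 1:2] - o[1:2])^2))
      if (tex > cur) {
        v[i, ] <- o + tex * dirr
        onSphere <- c(onSphere, i)
      }
    }
    if (length(onSphere) < 5)
      stop("synthetic femur: ", side,
           " bump under-sampled; refine meshResolution")
    bumpLab[[side]] <- onSphere
  }
  # snap landmark vertices to the exposed sphere poles (smooth interior
  # extrema: their discrete recovery error is second order)
  Ptro <- Ttro + c(0, 0, rtro)
  sn <- .snapVertex(v, bumpLab$trochanter, Ptro); v <- sn$v
  Ql <- Tl - c(0, 0, rt)
  sn <- .snapVertex(v, bumpLab$lateral, Ql); v <- sn$v
  # medial condylar sphere caudal/cranial poles for the depth extent
  condIdx <- which(vtag == "condyle")
  onM <- condIdx[abs(sqrt(rowSums(sweep(v[condIdx, , drop = FALSE], 2, cm)^2)) - rc) < 1e-6]
  sn <- .snapVertex(v, onM, cm + c(0, rc, 0)); v <- sn$v
  sn <- .snapVertex(v, onM, cm - c(0, rc, 0)); v <- sn$v

  # region labels (all from the construction: exact-on-primitive vertices)
  d2m <- sqrt(rowSums(sweep(v, 2, cm)^2))
  d2l <- sqrt(rowSums(sweep(v, 2, cl)^2))
  isCond <- seq_len(nrow(v)) %in% c(condIdx, np * length(rings) + 1)
  labels <- list(
    medial_condyle = which(isCond & abs(d2m - rc) < 1e-6),
    lateral_condyle = which(isCond & abs(d2l - rc) < 1e-6),
    femoral_head = which(vtag == "head" &
                           abs(sqrt(rowSums(sweep(v, 2, H)^2)) - rh) < 1e-6),
    femoral_neck = which(vtag == "neck"),
    diaphysis = which(vtag == "wall" & vz0 >= 62 & vz0 <= 163 &
                        !(vz0 > Tm[3] - rt - 2 & vz0 < Tm[3] + rt + 2) &
                        !(vz0 > Ttro[3] - rtro - 2)),
    greater_trochanter = sort(unique(bumpLab$trochanter)),
    medial_trochlear_tubercle = sort(unique(bumpLab$medial)),
    lateral_trochlear_tubercle = sort(unique(bumpLab$lateral))
  )

  mesh <- TriangleMesh(v * s, faces(mesh), labels, validate = FALSE)
  truth <- c(length = sqrt(sum((Ptro - Ql)^2)) * s,
             bicondylar_width = Wbc * s,
             medial_condylar_width = (dc + rc) * s,
             medial_condylar_depth = 2 * rc * s,
             medial_condylar_radius = rc * s,
             femoral_head_radius = rh * s,
             fma_angle = p$fmaAngle, neck_angle = p$neckAngle,
             tubercle_angle = p$tubercleAngle, version_angle = p$versionAngle)
  units <- c(rep("mm", 6), rep("deg", 4))
  names(units) <- names(truth)
  truthSet <- new("BiometricSet", bone = "femur", values = truth,
                  units = units, provenance = list(source = "synthetic"))
  list(mesh = mesh, truth = truthSet, params = p)
}

# ---- tibia ------------------------------------------------------------------

.makeTibia <- function(p) {
  s <- p$scale
  res <- p$meshResolution
  deg <- pi / 180
  a <- p$plateauWidth / 2 # ML half-axis
  b <- 40                  # CrCd half-axis
  tau <- p$ctpTilt * deg
  thM <- p$ctsMedial * deg
  thL <- p$ctsLateral * deg
  thBar <- (thM + thL) / 2
  rhoM <- 0.3 # intercondylar-eminence mesa: concentric raised ellipse
  h0 <- 8     # mesa height
  rsh <- 20   # shaft radius
  zNeck <- -60
  zShaftEnd <- -340
  capR <- rsh # distal hemispherical cap

  # facet slope as a function of x (blended across the mesa strip)
  xb <- rhoM * a
  slopeAt <- function(x) {
    if (x <= -xb) return(thM)
    if (x >= xb) return(thL)
    thM + (thL - thM) * (x + xb) / (2 * xb)
  }
  # the mesa sits on the mean-slope plane, raised by h0; its cliff edge is
  # the rho = rhoM ring, so the curvature border passes through sampled
  # vertices exactly
  plateauZ <- function(x, y, rho = 1) {
    if (rho <= rhoM + 1e-9) x * tan(tau) - y * tan(thBar) + h0
    else x * tan(tau) - y * tan(slopeAt(x))
  }

  np <- max(24, 4 * ceiling(pi * (a + b) / res / 4))
  phis <- 2 * pi * (seq_len(np) - 1) / np
  cph <- cos(phis); sph <- sin(phis)

  rings <- list(); ringTag <- character(0); ringRho <- numeric(0)
  addRing <- function(ring, tag, rho = NA) {
    rings[[length(rings) + 1]] <<- ring
    ringTag <<- c(ringTag, tag)
    ringRho <<- c(ringRho, rho)
  }
  # distal hemispherical cap (built bottom-up)
  nC <- max(4, ceiling(capR * (pi / 2) / res))
  gammas <- seq(pi / 2 - pi / 2 / nC / 2, 0.12, length.out = nC)
  zc <- zShaftEnd
  for (g in rev(gammas)) {
    addRing(cbind(capR * sin(g) * cph, capR * sin(g) * sph,
                  zc - capR * cos(g)), "cap")
  }
  # shaft
  nS <- ceiling((zNeck - zShaftEnd) / res)
  for (z in seq(zShaftEnd + (zNeck - zShaftEnd) / nS, zNeck,
                length.out = nS)) {
    addRing(cbind(rsh * cph, rsh * sph, z), "shaft", z)
  }
  # metaphyseal flare: circle to ellipse
  zRimBase <- -30
  nF <- max(3, ceiling((zRimBase - zNeck) / res))
  for (z in seq(zNeck + (zRimBase - zNeck) / nF, zRimBase, length.out = nF)) {
    w <- .smoothstep((z - zNeck) / (zRimBase - zNeck))
    ax <- (1 - w) * rsh + w * a
    bx <- (1 - w) * rsh + w * b
    addRing(cbind(ax * cph, bx * sph, z), "flare", z)
  }
  # blend up to the tilted/sloped rim so side-wall triangles stay squat
  rimZ <- vapply(seq_len(np), function(j)
    plateauZ(a * cph[j], b * sph[j]), numeric(1))
  nB <- max(3, ceiling((max(rimZ) - zRimBase) / res))
  for (k in seq_len(nB - 1)) {
    t <- k / nB
    addRing(cbind(a * cph, b * sph, (1 - t) * zRimBase + t * rimZ),
            "rimBlend", NA)
  }
  # plateau rings: rim (rho = 1) inward; rings at rho = 0.92 (landmark
  # ring) and rho = rhoM (mesa cliff edge) are guaranteed
  nP <- max(8, ceiling(a / res))
  rhos <- sort(unique(c(seq(1, 0.04, length.out = nP), 0.92, rhoM)),
               decreasing = TRUE)
  for (rho in rhos) {
    x <- rho * a * cph
    y <- rho * b * sph
    z <- vapply(seq_len(np), function(j) plateauZ(x[j], y[j], rho),
                numeric(1))
    addRing(cbind(x, y, z), "plateau", rho)
  }
  bottomApex <- c(0, 0, zc - capR)
  topApex <- c(0, 0, plateauZ(0, 0, 0))
  mesh <- .ringStack(rings, bottomApex, topApex)
  v <- vertices(mesh)
  vtag <- c(rep(ringTag, each = np), "apexB", "apexT")
  vrho <- c(rep(ringRho, each = np), NA, NA)
  plateauIdx <- which(vtag == "plateau")
  topApexIdx <- nrow(v)
  inMesa <- c(plateauIdx[vrho[plateauIdx] <= rhoM + 1e-9], topApexIdx)

  # snap landmarks (all on the plateau)
  rho92 <- plateauIdx[abs(vrho[plateauIdx] - 0.92) < 1e-9]
  xM <- -0.92 * a; xL <- 0.92 * a
  Mpt <- c(xM, 0, plateauZ(xM, 0))
  Lpt <- c(xL, 0, plateauZ(xL, 0))
  sn <- .snapVertex(v, rho92, Mpt); v <- sn$v; iM <- sn$index
  sn <- .snapVertex(v, rho92, Lpt); v <- sn$v; iL <- sn$index
  xd <- -22
  yd <- 0.92 * b * sqrt(1 - (xd / (0.92 * a))^2)
  snapMed <- list(c(xd, -yd, plateauZ(xd, -yd)), c(xd, yd, plateauZ(xd, yd)))
  for (tgt in snapMed) { sn <- .snapVertex(v, rho92, tgt); v <- sn$v }
  xdl <- 22
  ydl <- 0.92 * b * sqrt(1 - (xdl / (0.92 * a))^2)
  for (tgt in list(c(xdl, -ydl, plateauZ(xdl, -ydl)),
                   c(xdl, ydl, plateauZ(xdl, ydl)))) {
    sn <- .snapVertex(v, rho92, tgt); v <- sn$v
  }
  # mesa proximal landmark (most proximal point on the eminence): the cliff
  # edge point maximizing the tilted-plane height over the mesa ellipse
  phiStar <- atan2(-b * tan(thBar), a * tan(tau))
  Pm <- c(rhoM * a * cos(phiStar), rhoM * b * sin(phiStar), 0)
  Pm[3] <- Pm[1] * tan(tau) - Pm[2] * tan(thBar) + h0
  edgeRing <- plateauIdx[abs(vrho[plateauIdx] - rhoM) < 1e-9]
  sn <- .snapVertex(v, edgeRing, Pm); v <- sn$v

  labels <- list(
    micet = sort(unique(inMesa)),
    plateau_medial = plateauIdx[vrho[plateauIdx] <= 0.92 + 1e-9 &
                                  vrho[plateauIdx] >= 0.45 &
                                  v[plateauIdx, 1] <= xd + 1e-9],
    plateau_lateral = plateauIdx[vrho[plateauIdx] <= 0.92 + 1e-9 &
                                   vrho[plateauIdx] >= 0.45 &
                                   v[plateauIdx, 1] >= xdl - 1e-9],
    distal_ridge = which(v[, 3] <= zc - capR * 0.9),
    diaphysis = which(vtag == "shaft" & v[, 3] >= -300 & v[, 3] <= -100)
  )
  mesh <- TriangleMesh(v * s, faces(mesh), labels, validate = FALSE)
  truth <- c(length = sqrt(sum((Pm - bottomApex)^2)) * s,
             bicondylar_width = sqrt(sum((Lpt - Mpt)^2)) * s,
             medial_condylar_width = (0.92 - rhoM) * a * s,
             medial_condylar_depth = 2 * yd / cos(thM) * s,
             ctp_angle = 90 - p$ctpTilt,
             cts_medial = p$ctsMedial, cts_lateral = p$ctsLateral)
  units <- c(rep("mm", 4), rep("deg", 3))
  names(units) <- names(truth)
  truthSet <- new("BiometricSet", bone = "tibia", values = truth,
                  units = units, provenance = list(source = "synthetic"))
  list(mesh = mesh, truth = truthSet, params = p)
}

#' Generate a synthetic bone with region labels and analytic ground truth
#'
#' @param params a [SyntheticBoneParams()] list.
#' @return list with `mesh` (closed labelled [TriangleMesh-class]), `truth`
#'   (the analytic [BiometricSet-class]) and `params`.
#' @export
makeBone <- function(params) {
  stopifnot(inherits(params, "SyntheticBoneParams"))
  if (params$bone == "femur") .makeFemur(params) else .makeTibia(params)
}

#' Sample a synthetic bone population
#'
#' Draws bone parameters from a population specification that emulates a
#' scale-dominant bone population: uniform scale is lognormal (sdlog 0.08,
#' about +/-15 percent range over a small population) and the angles vary
#' independently around the reference values; the lateral caudal slope is
#' the medial slope plus a Gaussian offset (mean 6, SD 1 degrees).
#'
#' @param n population size (>= 3).
#' @param bone "femur" or "tibia".
#' @param spec named list overriding distribution settings: `scaleSdLog`,
#'   `neckSd`, `versionSd`, `fmaSd`, `tubercleSd`, `ctpSd`, `ctsMedialSd`,
#'   `ctsOffsetMean`, `ctsOffsetSd` (degrees), and `meshResolution`.
#' @param seed integer seed for reproducibility.
#' @return list of `makeBone` results (each with `mesh`, `truth`, `params`).
#' @export
samplePopulation <- function(n, bone = c("femur", "tibia"), spec = list(),
                             seed = 1) {
  bone <- match.arg(bone)
  stopifnot(n >= 3)
  def <- list(scaleSdLog = 0.08, neckSd = 2, versionSd = 2.5, fmaSd = 0.6,
              tubercleSd = 1.2, ctpSd = 0.5, ctsMedialSd = 0.8,
              ctsOffsetMean = 6, ctsOffsetSd = 1,
              meshResolution = if (bone == "femur") 6 else 5)
  def[names(spec)] <- spec
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- min(2, max(0.5, exp(stats::rnorm(1, 0, def$scaleSdLog))))
    p <- if (bone == "femur") {
      SyntheticBoneParams("femur", scale = sc,
        neckAngle = min(178, max(125, stats::rnorm(1, 157.3, def$neckSd))),
        versionAngle = min(85, max(5, stats::rnorm(1, 43.5, def$versionSd))),
        fmaAngle = min(25, max(0.5, stats::rnorm(1, 6.7, def$fmaSd))),
        tubercleAngle = min(29, max(12.5,
          stats::rnorm(1, 15.3, def$tubercleSd))),
        meshResolution = def$meshResolution)
    } else {
      med <- max(1, stats::rnorm(1, 9.6, def$ctsMedialSd))
      SyntheticBoneParams("tibia", scale = sc,
        ctpTilt = stats::rnorm(1, 1.1, def$ctpSd),
        ctsMedial = med,
        ctsLateral = med + max(0.5, stats::rnorm(1, def$ctsOffsetMean,
                                                 def$ctsOffsetSd)),
        meshResolution = def$meshResolution,
        allowInvertedSlopes = TRUE)
    }
    out[[i]] <- makeBone(p)
  }
  names(out) <- sprintf("%s%02d", bone, seq_len(n))
  out
}
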