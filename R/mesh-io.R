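# Surface-mesh file formats. Units are assumed to be millimetres throughout;
# STL/PLY/OBJ carry no unit metadata, so loadMesh() warns (not errors) when a
# bone-sized mesh looks implausibly small.

#' Read a triangle mesh from STL, PLY or OBJ
#'
#' STL is read in both binary and ASCII form and welded (STL stores each
#' triangle independently); PLY (ASCII or binary little-endian) and OBJ
#' preserve vertex order, so PLY round-trips corresponded meshes exactly.
#'
#' @param path file path.
#' @param format "stl", "ply" or "obj"; inferred from the extension when
#'   missing.
#' @param validate check manifold-orientability after load.
#' @param warnSmall warn if the bounding-box diagonal is below 50 mm (bones
#'   are expected in mm).
#' @return a [TriangleMesh-class].
#' @export
loadMesh <- function(path, format = NULL, validate = TRUE, warnSmall = TRUE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "ply", "obj"))
  mesh <- switch(format,
                 stl = .readSTL(path),
                 ply = .readPLY(path),
                 obj = .readOBJ(path))
  if (validate && nFaces(mesh) > 0) {
    chk <- .edgeManifoldCheck(faces(mesh))
    if (!chk$orientable)
      stop("mesh in ", path, " is not manifold-orientable: ", chk$diagnostic)
  }
  if (warnSmall && nVertices(mesh) > 0) {
    diag <- sqrt(sum((apply(vertices(mesh), 2, max) -
                      apply(vertices(mesh), 2, min))^2))
    if (diag < 50)
      warning("bounding-box diagonal ", sprintf("%.1f", diag),
              " mm: units are assumed mm and bones are expected > 50 mm")
  }
  mesh
}

#' Write a triangle mesh to STL, PLY or OBJ
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output path.
#' @param format "stl", "ply" or "obj"; inferred from the extension when
#'   missing.
#' @param binary write binary STL / binary little-endian PLY (default TRUE;
#'   ignored for OBJ).
#' @return `path`, invisibly.
#' @export
saveMesh <- function(mesh, path, format = NULL, binary = TRUE) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(tolower(format), c("stl", "ply", "obj"))
  switch(format,
         stl = .writeSTL(mesh, path, binary),
         ply = .writePLY(mesh, path, binary),
         obj = .writeOBJ(mesh, path))
  invisible(path)
}

.readSTL <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 512)
  txt <- rawToChar(head[head != as.raw(0)])
  isAscii <- grepl("^\\s*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, useBytes = TRUE)
  close(con)
  on.exit(NULL)
  if (isAscii) .readSTLascii(path) else .readSTLbinary(path)
}

.readSTLascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (!length(vl)) stop("malformed ASCII STL (no vertex records): ", path)
  nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x)
    suppressWarnings(as.numeric(x[2:4])))
  v <- do.call(rbind, nums)
  if (anyNA(v) || nrow(v) %% 3 != 0)
    stop("malformed ASCII STL (vertex count ", nrow(v),
         " not a multiple of 3): ", path)
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  weldVertices(TriangleMesh(v, f, validate = FALSE))
}

.readSTLbinary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  nf <- readBin(con, "integer", 1, size = 4, endian = "little")
  expected <- 84 + nf * 50
  if (sz < expected)
    stop(sprintf("truncated binary STL: %d faces declared need %d bytes, file has %d (truncated at byte offset %d): %s",
                 nf, expected, sz, sz, path))
  raw <- readBin(con, "raw", nf * 50)
  m <- matrix(raw, nrow = 50)
  tri <- readBin(as.vector(m[1:48, ]), "double", n = nf * 12, size = 4,
                 endian = "little")
  tm <- matrix(tri, ncol = 12, byrow = TRUE) # nx ny nz v1 v2 v3
  v <- matrix(t(tm[, 4:12]), ncol = 3, byrow = TRUE)
  f <- matrix(seq_len(nrow(v)), ncol = 3, byrow = TRUE)
  weldVertices(TriangleMesh(v, f, validate = FALSE))
}

.writeSTL <- function(mesh, path, binary) {
  v <- vertices(mesh)
  f <- faces(mesh)
  n <- .faceCross(v, f)
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    block <- t(cbind(n, v[f[, 1], ], v[f[, 2], ], v[f[, 3], ]))
    for (i in seq_len(nrow(f))) {
      writeBin(block[, i], con, size = 4, endian = "little")
      writeBin(as.integer(0), con, size = 2, endian = "little")
    }
  } else {
    out <- c("solid mesh",
             unlist(lapply(seq_len(nrow(f)), function(i) c(
               sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
               "    outer loop",
               sprintf("      vertex %.9g %.9g %.9g",
                       v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
               "    endloop",
               "  endfacet"))),
             "endsolid mesh")
    writeLines(out, path)
  }
}

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, 1)
    if (!length(ln)) stop("malformed PLY (no end_header): ", path)
    hdr <- c(hdr, ln)
    if (grepl("^end_header", ln)) break
  }
  fmt <- sub("^format\\s+", "", grep("^format", hdr, value = TRUE)[1])
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", hdr,
                                                value = TRUE)[1]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", hdr,
                                              value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  # vertex property names in declared order
  vi <- grep("^element vertex", hdr)
  fi <- grep("^element face", hdr)
  vprops <- hdr[seq(vi + 1, fi - 1)]
  vprops <- grep("^property", vprops, value = TRUE)
  pparts <- strsplit(trimws(vprops), "\\s+")
  pnames <- vapply(pparts, function(x) x[3], "")
  ptypes <- vapply(pparts, function(x) x[2], "")
  xyz <- match(c("x", "y", "z"), pnames)
  if (anyNA(xyz)) stop("PLY without x/y/z vertex properties: ", path)
  if (grepl("^ascii", fmt)) {
    dat <- scan(con, what = numeric(), n = nv * length(pnames), quiet = TRUE)
    v <- matrix(dat, ncol = length(pnames), byrow = TRUE)[, xyz, drop = FALSE]
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- scan(con, what = integer(), n = 1, quiet = TRUE)
      idx <- scan(con, what = integer(), n = cnt, quiet = TRUE)
      if (cnt != 3) stop("non-triangular PLY face (", cnt, " vertices): ", path)
      f[i, ] <- idx + 1L
    }
  } else if (grepl("^binary_little_endian", fmt)) {
    sizes <- c(char = 1, uchar = 1, int8 = 1, uint8 = 1, short = 2,
               ushort = 2, int16 = 2, uint16 = 2, int = 4, uint = 4,
               int32 = 4, uint32 = 4, float = 4, float32 = 4, double = 8,
               float64 = 8)
    if (!all(ptypes %in% c("float", "float32")))
      stop("binary PLY supported for float32 vertex properties only: ", path)
    vraw <- readBin(con, "raw", nv * 4 * length(pnames))
    vall <- readBin(vraw, "double", n = nv * length(pnames), size = 4,
                    endian = "little")
    v <- matrix(vall, ncol = length(pnames), byrow = TRUE)[, xyz, drop = FALSE]
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", 1))
      if (cnt != 3) stop("non-triangular PLY face (", cnt, " vertices): ", path)
      f[i, ] <- readBin(con, "integer", 3, size = 4, endian = "little") + 1L
    }
  } else {
    stop("unsupported PLY format '", fmt, "': ", path)
  }
  TriangleMesh(v, f, validate = FALSE)
}

.writePLY <- function(mesh, path, binary) {
  v <- vertices(mesh)
  f <- faces(mesh)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           paste("element vertex", nrow(v)),
           "property float x", "property float y", "property float z",
           paste("element face", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.vector(t(v)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl)) stop("malformed OBJ (no vertices): ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
    as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*", "", x[-1]))
    if (length(idx) != 3) stop("non-triangular OBJ face: ", path)
    idx
  }))
  TriangleMesh(v, f, validate = FALSE)
}

.writeOBJ <- function(mesh, path) {
  v <- vertices(mesh)
  f <- faces(mesh)
  writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])), path)
}

#' Read / write region annotations (JSON, 0-based indices on disk)
#'
#' Region files map region names to vertex-index arrays. On disk indices are
#' 0-based (the common exchange convention); in memory they are 1-based.
#' @param path JSON file path.
#' @return named list of 1-based integer vectors.
#' @export
loadRegions <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(raw, function(idx) as.integer(idx) + 1L)
}

#' @rdname loadRegions
#' @param regions named list of 1-based integer vectors.
#' @export
saveRegions <- function(regions, path) {
  jsonlite::write_json(lapply(regions, function(idx) as.integer(idx) - 1L),
                       path)
  invisible(path)
}
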