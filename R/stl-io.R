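#' Construct a triangle mesh
#'
#' @param vertices m x 3 numeric matrix (mm)
#' @param faces k x 3 integer matrix, 1-based
#' @return a \code{\linkS4class{TriangleMesh}}
#' @export
TriangleMesh <- function(vertices, faces) {
  new("TriangleMesh",
      vertices = matrix(as.numeric(vertices), ncol = 3,
                        dimnames = NULL),
      faces = matrix(as.integer(faces), ncol = 3, dimnames = NULL))
}

# Merge coincident vertices of a triangle soup into an indexed mesh.
.dedupVertices <- function(tris) {
  key <- paste(tris[, 1], tris[, 2], tris[, 3], sep = "/")
  uid <- !duplicated(key)
  idx <- match(key, key[uid])
  list(vertices = tris[uid, , drop = FALSE],
       faces = matrix(idx, ncol = 3, byrow = TRUE))
}

#' Read an STL file (binary or ASCII)
#'
#' Units are assumed to be mm. A non-watertight mesh is read with a warning;
#' volume operations will later refuse it.
#'
#' @param path file path
#' @return a \code{\linkS4class{TriangleMesh}}
#' @export
readSTL <- function(path) {
  if (!file.exists(path)) stop("STL file not found: ", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head <- readBin(con, "raw", n = min(512, sz))
  close(con)
  txt <- rawToChar(head[head != as.raw(0)])
  isAscii <- grepl("^[ \t\r\n]*solid", txt, useBytes = TRUE) &&
    grepl("facet", txt, fixed = TRUE, useBytes = TRUE)
  if (isAscii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(x) as.numeric(x[2:4]))
    tris <- do.call(rbind, nums)
    if (is.null(tris) || nrow(tris) %% 3 != 0)
      stop("malformed ASCII STL: vertex count not a multiple of 3")
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (is.na(nt) || nt < 0 || sz < 84 + nt * 50)
      stop("truncated or malformed binary STL: ", path)
    rec <- readBin(con, "raw", n = nt * 50)
    m <- matrix(rec, nrow = 50)
    flt <- apply(m[1:48, , drop = FALSE], 2, function(col)
      readBin(col, "numeric", n = 12, size = 4, endian = "little"))
    # rows 4:12 of each record are the three vertices
    flt <- matrix(flt, nrow = 12)
    tris <- matrix(as.vector(flt[4:12, , drop = FALSE]), ncol = 3, byrow = TRUE)
  }
  d <- .dedupVertices(tris)
  mesh <- TriangleMesh(d$vertices, d$faces)
  if (!isWatertight(mesh))
    warning("mesh read from ", basename(path),
            " is not watertight; volume operations will refuse it")
  mesh
}

#' Write an STL file
#'
#' @param mesh a \code{TriangleMesh}
#' @param path output file
#' @param ascii write ASCII STL instead of binary
#' @export
writeSTL <- function(mesh, path, ascii = FALSE) {
  V <- mesh@vertices
  F <- mesh@faces
  n <- .faceNormals(mesh)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid slicerQC", con)
    for (i in seq_len(nrow(F))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        v <- V[F[i, k], ]
        writeLines(sprintf("      vertex %.9g %.9g %.9g", v[1], v[2], v[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid slicerQC", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(c(n[i, ], t(V[F[i, ], ])), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  }
  invisible(path)
}

# unit face normals
.faceNormals <- function(mesh) {
  V <- mesh@vertices
  F <- mesh@faces
  a <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  b <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  n <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
             a[, 3] * b[, 1] - a[, 1] * b[, 3],
             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Export a staged point cloud
#'
#' Writes either a plain XYZ table or an ASCII PLY with per-vertex stage,
#' role and layer attributes for QC visualisation.
#'
#' @param pc a \code{StagedPointCloud}
#' @param path output file
#' @param format \code{"xyz"} or \code{"ply"}
#' @export
writePointCloud <- function(pc, path, format = c("xyz", "ply")) {
  format <- match.arg(format)
  p <- pc@coords
  if (format == "xyz") {
    utils::write.table(p, path, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("comment stage", pc@stage, "role", pc@role),
                 paste("element vertex", nrow(p)),
                 "property float x", "property float y", "property float z",
                 "property int layer", "end_header"), con)
    utils::write.table(cbind(p, pc@layerIndex), con,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
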