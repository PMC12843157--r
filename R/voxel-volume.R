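#' Rasterize a centerline point cloud into a voxel occupancy map
#'
#' The PC1 nozzle-centerline points are stamped into a regular grid
#' (half-open voxel membership), and the occupancy is then morphologically
#' closed with a cube kernel of radius \code{closingRadius} so that adjacent
#' extrusion lines (spacing = line width \eqn{w}) fuse into a solid. The
#' closed solid's surface is the centerline envelope, which the subsequent
#' \eqn{-w/2} XY offset corrects onto the true filament boundary. The grid
#' always includes an empty margin around all occupied voxels and its origin
#' is snapped to a multiple of the voxel size, so results are reproducible
#' across runs and under grid-aligned translations.
#'
#' @param pc1 a \code{StagedPointCloud} (stage PC1, non-empty)
#' @param meta list with \code{lineWidth} and \code{layerHeight} (mm), as
#'   returned in \code{GCodeToolpath} meta
#' @param voxelSize voxel edge (mm), default 0.10; must be
#'   <= min(w, h) / 2
#' @param closingRadius closing kernel radius (mm); default \code{w / 2}
#' @param maxCells guard against runaway grids
#' @return an unclassified \code{\linkS4class{VoxelLabelMap}}
#' @export
voxelize <- function(pc1, meta, voxelSize = 0.1, closingRadius = NULL,
                     maxCells = 4e8) {
  if (nPoints(pc1) == 0) stop("empty point cloud: nothing to voxelize")
  w <- meta$lineWidth; h <- meta$layerHeight
  if (voxelSize > min(w, h) / 2 + 1e-12)
    stop("voxelSize must be <= min(line width, layer height) / 2")
  if (is.null(closingRadius)) closingRadius <- w / 2
  p <- pc1@coords
  r <- as.integer(round(closingRadius / voxelSize))
  marginMm <- closingRadius + 2 * voxelSize
  lo <- floor((apply(p, 2, min) - marginMm) / voxelSize) * voxelSize
  hi <- apply(p, 2, max) + marginMm
  dims <- as.integer(ceiling((hi - lo) / voxelSize) + 1)
  if (prod(as.numeric(dims)) > maxCells)
    stop(sprintf(paste0("voxel grid of %d x %d x %d cells exceeds the budget; ",
                        "suggested voxel size >= %.3f mm"),
                 dims[1], dims[2], dims[3],
                 voxelSize * (prod(as.numeric(dims)) / maxCells)^(1 / 3)))
  occ <- cpp_stamp_points(p, lo, voxelSize, dims)
  occ <- cpp_binary_close(occ, dims, r)
  new("VoxelLabelMap", labels = occ, dims = dims, origin = as.numeric(lo),
      voxelSize = voxelSize, closingRadius = closingRadius,
      classified = FALSE)
}

#' Build a label map directly from a logical/integer occupancy array
#'
#' Mainly for tests and synthetic label-map construction; adds the required
#' one-voxel empty margin if the array touches its border.
#'
#' @param arr 3D array; non-zero entries are occupied
#' @param voxelSize voxel edge (mm)
#' @param origin grid corner (mm)
#' @export
voxelMapFromArray <- function(arr, voxelSize = 0.1, origin = c(0, 0, 0)) {
  d <- dim(arr)
  stopifnot(length(d) == 3)
  occ <- arr != 0
  pad <- any(occ[c(1, d[1]), , ]) || any(occ[, c(1, d[2]), ]) ||
    any(occ[, , c(1, d[3])])
  if (pad) {
    a2 <- array(FALSE, d + 2L)
    a2[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
    occ <- a2
    d <- d + 2L
    origin <- origin - voxelSize
  }
  new("VoxelLabelMap", labels = as.raw(as.integer(occ)), dims = as.integer(d),
      origin = as.numeric(origin), voxelSize = voxelSize,
      closingRadius = 0, classified = FALSE)
}

#' Classify occupied voxels into SHELL and INTERIOR
#'
#' The exterior empty region is found by a 6-connected flood fill from the
#' grid boundary; occupied voxels 26-adjacent to the exterior become SHELL
#' and the remaining occupied voxels become INTERIOR. Enclosed empty
#' cavities that survived the closing stay EMPTY (they are not exterior).
#' Idempotent.
#'
#' @param map a \code{VoxelLabelMap}
#' @return the classified map
#' @export
classifyLabels <- function(map) {
  occ <- as.raw(as.integer(map@labels != .L_EMPTY))
  lab <- cpp_classify(occ, map@dims)
  initialize(map, labels = lab, classified = TRUE)
}

#' Voxel indices of points (1-based; NA outside the grid)
#'
#' Half-open membership [lo, hi): a point exactly on a voxel boundary belongs
#' to the upper voxel.
#'
#' @param map a \code{VoxelLabelMap}
#' @param pts n x 3 matrix
#' @return n x 3 integer matrix
#' @export
voxelIndexOf <- function(map, pts) {
  pts <- matrix(pts, ncol = 3)
  idx <- floor(sweep(sweep(pts, 2, map@origin), 2, map@voxelSize, "/") + 1e-6) + 1
  bad <- idx[, 1] < 1 | idx[, 2] < 1 | idx[, 3] < 1 |
    idx[, 1] > map@dims[1] | idx[, 2] > map@dims[2] | idx[, 3] > map@dims[3]
  idx[bad, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

# linear index into the raw label vector (NA-safe)
.voxLinear <- function(map, idx) {
  (idx[, 3] - 1) * as.numeric(map@dims[1]) * map@dims[2] +
    (idx[, 2] - 1) * as.numeric(map@dims[1]) + idx[, 1]
}

#' Per-point voxel label
#'
#' @param map a classified \code{VoxelLabelMap}
#' @param pts n x 3 matrix
#' @return integer vector: 0 EMPTY (also for points outside the grid),
#'   1 INTERIOR, 2 SHELL
#' @export
voxelLabelAt <- function(map, pts) {
  idx <- voxelIndexOf(map, pts)
  lin <- .voxLinear(map, idx)
  out <- integer(nrow(idx))
  ok <- !is.na(lin)
  out[ok] <- as.integer(map@labels[lin[ok]])
  out
}

#' Is a point inside the infill?
#'
#' TRUE iff the containing voxel is labelled INTERIOR. Points outside the
#' grid, in EMPTY voxels, or in SHELL voxels are not infill.
#'
#' @param pts n x 3 matrix (or length-3 vector)
#' @param map a classified \code{VoxelLabelMap}
#' @return logical vector
#' @export
isInfill <- function(pts, map) {
  if (!map@classified) stop("label map must be classified first")
  voxelLabelAt(map, pts) == 1L
}

#' Export a label map as an NRRD volume (debug/QC)
#'
#' Single-file NRRD with uint8 labels, axis order x,y,z and mm spacing, for
#' visual inspection in standard volume viewers.
#'
#' @param map a \code{VoxelLabelMap}
#' @param path output file (.nrrd)
#' @export
writeLabelMapNRRD <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# slicerQC voxel label map (0 empty, 1 interior, 2 shell)",
           "type: uint8",
           "dimension: 3",
           sprintf("sizes: %d %d %d", map@dims[1], map@dims[2], map@dims[3]),
           sprintf("spacings: %g %g %g", map@voxelSize, map@voxelSize,
                   map@voxelSize),
           "space: left-posterior-superior",
           sprintf("space origin: (%g,%g,%g)", map@origin[1] +
                     map@voxelSize / 2, map@origin[2] + map@voxelSize / 2,
                   map@origin[3] + map@voxelSize / 2),
           "encoding: raw", "endian: little", "")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(map@labels, con)
  invisible(path)
}

#' Extract a watertight iso-surface from the occupancy
#'
#' Iso-level 0.5 on the binary occupancy of the voxel-center lattice, using a
#' tetrahedral decomposition (six tetrahedra per cell, midpoint
#' interpolation). The empty margin guarantees a closed surface; faces are
#' oriented outward; vertices are in mm world coordinates.
#'
#' @param map a \code{VoxelLabelMap} with at least one occupied voxel
#' @return a \code{\linkS4class{TriangleMesh}}
#' @export
marchingCubesSurface <- function(map) {
  occ <- as.raw(as.integer(map@labels != .L_EMPTY))
  if (!any(occ != as.raw(0))) stop("empty label map: no occupied voxels")
  res <- cpp_marching_tetra(occ, map@dims, map@origin, map@voxelSize)
  mesh <- TriangleMesh(res$vertices, res$faces)
  if (!isWatertight(mesh))
    stop("internal error: iso-surface is not watertight")
  mesh
}

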