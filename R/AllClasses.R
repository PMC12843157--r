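#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib slicerQC, .registration = TRUE
NULL

.STAGES <- c("PC1", "PC2", "PC3", "PC4")
.ROLES <- c("UNSPLIT", "MODEL", "CALIBRATION", "TPCM")

# voxel label codes (raw), shared with the C++ side
.L_EMPTY <- as.raw(0L)
.L_INTERIOR <- as.raw(1L)
.L_SHELL <- as.raw(2L)

#' Toolpath parsed from G-code
#'
#' Ordered extrusion segments and travel moves recovered from a RepRap-style
#' linear-move G-code file, together with the process metadata (layer height
#' \eqn{h}, line width \eqn{w}, extrusion multiplier) extracted from the
#' slicer header or supplied as defaults.
#'
#' @slot segments data.frame with columns \code{x1,y1,z1,x2,y2,z2} (mm),
#'   \code{de} (extruded filament, mm, > 0), \code{layer} (0-based layer
#'   index), \code{pathId} (contiguous extrusion path id) and \code{feature}
#'   (slicer feature tag such as \code{WALL-OUTER}, or \code{NA}).
#' @slot travels data.frame of non-extruding moves (\code{x1..z2}).
#' @slot meta list with \code{layerHeight}, \code{lineWidth},
#'   \code{extrusionMultiplier}, \code{sourceDialect} and \code{metaSource}.
#' @export
setClass("GCodeToolpath", representation(
  segments = "data.frame",
  travels = "data.frame",
  meta = "list"
), validity = function(object) {
  msg <- character()
  need <- c("x1","y1","z1","x2","y2","z2","de","layer","pathId")
  if (!all(need %in% names(object@segments)))
    msg <- c(msg, "segments must have columns x1..z2, de, layer, pathId")
  else if (nrow(object@segments)) {
    if (any(object@segments$de <= 0)) msg <- c(msg, "all de must be > 0")
    if (any(object@segments$z1 != object@segments$z2))
      msg <- c(msg, "extrusion segments must be planar (z1 == z2)")
    if (is.unsorted(object@segments$layer))
      msg <- c(msg, "layer index must be non-decreasing")
  }
  h <- object@meta$layerHeight; w <- object@meta$lineWidth
  if (!is.numeric(h) || h <= 0) msg <- c(msg, "meta$layerHeight must be > 0")
  if (!is.numeric(w) || w <= 0) msg <- c(msg, "meta$lineWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' Staged point cloud
#'
#' Points sampled along the G-code toolpath, carrying their chain links
#' (previous/next point in G-code order, broken at travels), per-point layer
#' index, the local in-plane unit tangent estimated from the neighbouring
#' G-code vertices, and the processing stage tag:
#' \code{PC1} raw nozzle centerline, \code{PC2} shell-filtered,
#' \code{PC3} XY-offset-corrected, \code{PC4} Z-corrected.
#'
#' @slot coords n x 3 numeric matrix (mm).
#' @slot prevIdx,nextIdx integer links to the neighbouring cloud points along
#'   the G-code path (\code{NA} at path breaks or for off-chain points).
#' @slot layerIndex integer per-point 0-based layer.
#' @slot pathId integer contiguous-path id per point.
#' @slot tangent n x 2 unit tangent in the layer plane (\code{NA} if unusable).
#' @slot feature character slicer feature tag per point (may be \code{NA}).
#' @slot stage one of \code{"PC1".."PC4"}.
#' @slot role one of \code{"UNSPLIT"}, \code{"MODEL"}, \code{"CALIBRATION"},
#'   \code{"TPCM"}.
#' @slot diagnostics list of stage diagnostics (drop counts etc.).
#' @export
setClass("StagedPointCloud", representation(
  coords = "matrix",
  prevIdx = "integer",
  nextIdx = "integer",
  layerIndex = "integer",
  pathId = "integer",
  tangent = "matrix",
  feature = "character",
  stage = "character",
  role = "character",
  diagnostics = "list"
), validity = function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must be n x 3")
  if (length(object@prevIdx) != n || length(object@nextIdx) != n)
    msg <- c(msg, "link vectors must match point count")
  if (!(object@stage %in% .STAGES)) msg <- c(msg, "invalid stage tag")
  if (!(object@role %in% .ROLES)) msg <- c(msg, "invalid role tag")
  ok <- which(!is.na(object@prevIdx))
  if (length(ok) && any(object@nextIdx[object@prevIdx[ok]] != ok, na.rm = TRUE))
    msg <- c(msg, "links must be mutual: next(prev(i)) == i")
  if (length(msg)) msg else TRUE
})

#' Voxel label map
#'
#' Regular 3D grid over the toolpath, labelling each voxel \code{EMPTY},
#' \code{INTERIOR} (infill) or \code{SHELL}. The grid always carries an empty
#' margin around all occupied voxels, and voxel membership is half-open
#' \code{[lo, hi)}.
#'
#' @slot labels raw vector of length \code{prod(dims)} with codes
#'   0 = EMPTY, 1 = INTERIOR, 2 = SHELL.
#' @slot dims integer (nx, ny, nz).
#' @slot origin numeric (x, y, z) of the corner of voxel (1,1,1), mm.
#' @slot voxelSize voxel edge length, mm.
#' @slot closingRadius morphological closing radius used, mm.
#' @slot classified logical; \code{TRUE} after \code{\link{classifyLabels}}.
#' @export
setClass("VoxelLabelMap", representation(
  labels = "raw",
  dims = "integer",
  origin = "numeric",
  voxelSize = "numeric",
  closingRadius = "numeric",
  classified = "logical"
), validity = function(object) {
  msg <- character()
  if (length(object@dims) != 3 || any(object@dims < 1))
    msg <- c(msg, "dims must be three positive integers")
  if (length(object@labels) != prod(as.numeric(object@dims)))
    msg <- c(msg, "labels length must equal prod(dims)")
  if (object@voxelSize <= 0) msg <- c(msg, "voxelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Triangle mesh
#'
#' A triangle surface in mm units: the reference STL, the marching-cubes QC
#' surface, or the layer-extruded reconstruction.
#'
#' @slot vertices m x 3 numeric matrix.
#' @slot faces k x 3 integer matrix of 1-based vertex indices.
#' @export
setClass("TriangleMesh", representation(
  vertices = "matrix",
  faces = "matrix"
), validity = function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3) msg <- c(msg, "vertices must be m x 3")
  if (ncol(object@faces) != 3) msg <- c(msg, "faces must be k x 3")
  if (nrow(object@faces) &&
      (min(object@faces) < 1 || max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (length(msg)) msg else TRUE
})

#' Rigid transform
#'
#' Rotation plus translation (no scaling, no reflection), as recovered by the
#' calibration-object registration.
#'
#' @slot rotation 3 x 3 orthonormal matrix with det = +1.
#' @slot translation numeric length-3 (mm).
#' @export
setClass("RigidTransform", representation(
  rotation = "matrix",
  translation = "numeric"
), validity = function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3, 3))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msg <- c(msg, "rotation must be orthonormal (R'R = I within 1e-9)")
    if (det(R) < 0) msg <- c(msg, "reflections are not rigid transforms")
  }
  if (length(object@translation) != 3) msg <- c(msg, "translation must be length 3")
  if (length(msg)) msg else TRUE
})

#' Deviation report
#'
#' Signed surface-distance statistics of a registered point cloud against the
#' reference mesh, and the volume difference between the layer-extruded
#' reconstruction and the reference.
#'
#' @slot msd signed mean surface distance (mm).
#' @slot rms root mean square distance (mm).
#' @slot dMin,dMax signed extrema (mm).
#' @slot nPoints number of compared points.
#' @slot volumeRef,volumeRecon volumes (mm^3); \code{NA} if not computed.
#' @slot volumeDiff reconstructed minus reference volume (mm^3).
#' @slot volumeDiffRel relative volume difference (%).
#' @slot diagnostics list (configuration, drop counts, per-layer table, ...).
#' @export
setClass("DeviationReport", representation(
  msd = "numeric", rms = "numeric", dMin = "numeric", dMax = "numeric",
  nPoints = "integer",
  volumeRef = "numeric", volumeRecon = "numeric",
  volumeDiff = "numeric", volumeDiffRel = "numeric",
  diagnostics = "list"
), validity = function(object) {
  msg <- character()
  if (!is.na(object@msd) && !is.na(object@rms)) {
    if (object@rms < abs(object@msd) - 1e-12)
      msg <- c(msg, "rms must be >= |msd|")
    if (!is.na(object@dMin) && !is.na(object@dMax) &&
        (object@dMin > object@msd + 1e-12 || object@msd > object@dMax + 1e-12))
      msg <- c(msg, "dMin <= msd <= dMax must hold")
  }
  if (length(msg)) msg else TRUE
})

#' Layer contour set
#'
#' Closed 2D polygons (outer boundaries CCW, holes CW, even-odd nesting)
#' traced from the corrected point cloud of one layer, plus the open chains
#' that failed to close (diagnostics).
#'
#' @slot layerIndex 0-based layer.
#' @slot zBottom,zTop slab extent, \code{zTop - zBottom = h}.
#' @slot contours list of n x 2 matrices (closed polygons, no repeated last
#'   vertex).
#' @slot openChains list of n x 2 matrices.
#' @export
setClass("LayerContourSet", representation(
  layerIndex = "integer",
  zBottom = "numeric",
  zTop = "numeric",
  contours = "list",
  openChains = "list"
))

#' Synthetic fixture scene
#'
#' A model solid plus the step calibration object, composed with a rigid
#' placement that emulates a slicer's unknown coordinate system, and the
#' slicing parameters used by the deterministic mini-slicer.
#'
#' @slot modelMesh,coMesh \code{TriangleMesh} in scene (placed) coordinates.
#' @slot modelRef,coRef \code{TriangleMesh} in reference coordinates (before
#'   placement) -- the ground truth the pipeline is compared against.
#' @slot placement ground-truth \code{RigidTransform} applied to the scene.
#' @slot slicingParams list: \code{h}, \code{w}, \code{nPerimeters},
#'   \code{infillOverlap}, \code{seed}.
#' @export
setClass("FixtureScene", representation(
  modelMesh = "TriangleMesh",
  coMesh = "TriangleMesh",
  modelRef = "TriangleMesh",
  coRef = "TriangleMesh",
  placement = "RigidTransform",
  slicingParams = "list"
))

# ---- show methods ----------------------------------------------------------

setMethod("show", "GCodeToolpath", function(object) {
  cat("GCodeToolpath:", nrow(object@segments), "extrusion segments,",
      nrow(object@travels), "travels\n")
  cat(sprintf("  layers: %d | h = %.3f mm | w = %.3f mm (meta from %s)\n",
              length(unique(object@segments$layer)),
              object@meta$layerHeight, object@meta$lineWidth,
              object@meta$metaSource))
})

setMethod("show", "StagedPointCloud", function(object) {
  cat(sprintf("StagedPointCloud [%s/%s]: %d points, %d layers\n",
              object@stage, object@role, nrow(object@coords),
              length(unique(object@layerIndex))))
})

setMethod("show", "VoxelLabelMap", function(object) {
  occ <- sum(object@labels != .L_EMPTY)
  cat(sprintf("VoxelLabelMap: %d x %d x %d @ %.3f mm (%s)\n",
              object@dims[1], object@dims[2], object@dims[3],
              object@voxelSize,
              if (object@classified) "classified" else "occupancy only"))
  cat(sprintf("  occupied voxels: %d", occ))
  if (object@classified)
    cat(sprintf(" (shell %d, interior %d)",
                sum(object@labels == .L_SHELL),
                sum(object@labels == .L_INTERIOR)))
  cat("\n")
})

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "DeviationReport", function(object) {
  cat("DeviationReport\n")
  cat(sprintf("  MSD %.4f mm | RMS %.4f mm | min %.4f | max %.4f | n = %d\n",
              object@msd, object@rms, object@dMin, object@dMax, object@nPoints))
  if (!is.na(object@volumeRef))
    cat(sprintf("  volume: recon %.3f vs ref %.3f mm^3 (%+.3f mm^3, %+.3f%%)\n",
                object@volumeRecon, object@volumeRef, object@volumeDiff,
                object@volumeDiffRel))
})

setMethod("show", "FixtureScene", function(object) {
  cat("FixtureScene: model +", "calibration object\n")
  cat(sprintf("  h = %.2f mm, w = %.2f mm, %d perimeters\n",
              object@slicingParams$h, object@slicingParams$w,
              object@slicingParams$nPerimeters))
})
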