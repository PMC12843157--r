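# Accessors for the S4 containers. Slot access outside the package should go
# through these.

#' Point coordinates of a staged cloud
#' @param x a \code{StagedPointCloud}
#' @return n x 3 numeric matrix (mm)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname coords
#' @export
setMethod("coords", "StagedPointCloud", function(x) x@coords)

#' Stage tag of a staged cloud
#' @param x a \code{StagedPointCloud}
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname stage
#' @export
setMethod("stage", "StagedPointCloud", function(x) x@stage)

#' Role tag of a staged cloud
#' @param x a \code{StagedPointCloud}
#' @export
setGeneric("cloudRole", function(x) standardGeneric("cloudRole"))

#' @rdname cloudRole
#' @export
setMethod("cloudRole", "StagedPointCloud", function(x) x@role)

#' Number of points
#' @param x a \code{StagedPointCloud}
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname nPoints
#' @export
setMethod("nPoints", "StagedPointCloud", function(x) nrow(x@coords))

#' Mesh vertices
#' @param x a \code{TriangleMesh}
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))

#' @rdname meshVertices
#' @export
setMethod("meshVertices", "TriangleMesh", function(x) x@vertices)

#' Mesh faces (1-based triangle indices)
#' @param x a \code{TriangleMesh}
#' @export
setGeneric("meshFaces", function(x) standardGeneric("meshFaces"))

#' @rdname meshFaces
#' @export
setMethod("meshFaces", "TriangleMesh", function(x) x@faces)

#' Voxel labels as a 3D array
#' @param x a \code{VoxelLabelMap}
#' @return integer array (nx, ny, nz): 0 EMPTY, 1 INTERIOR, 2 SHELL
#' @export
setGeneric("voxelLabels", function(x) standardGeneric("voxelLabels"))

#' @rdname voxelLabels
#' @export
setMethod("voxelLabels", "VoxelLabelMap", function(x) {
  array(as.integer(x@labels), dim = x@dims)
})

#' Report as a one-row data.frame
#' @param x a \code{DeviationReport}
#' @export
setGeneric("reportTable", function(x) standardGeneric("reportTable"))

#' @rdname reportTable
#' @export
setMethod("reportTable", "DeviationReport", function(x) {
  data.frame(msd = x@msd, rms = x@rms, d_min = x@dMin, d_max = x@dMax,
             n_points = x@nPoints, volume_ref = x@volumeRef,
             volume_recon = x@volumeRecon, volume_diff = x@volumeDiff,
             volume_diff_rel = x@volumeDiffRel)
})
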