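# Re-thread sequential chain links after filtering: surviving points of the
# same contiguous path are linked in original order.
.rethreadLinks <- function(pathId) {
  n <- length(pathId)
  prv <- c(NA_integer_, seq_len(max(n - 1, 0)))
  nxt <- c(seq_len(n)[-1], NA_integer_)
  if (n > 1) {
    brk <- which(diff(pathId) != 0)
    nxt[brk] <- NA_integer_
    prv[brk + 1L] <- NA_integer_
  }
  if (n == 1) { prv <- NA_integer_; nxt <- NA_integer_ }
  list(prv = as.integer(prv), nxt = as.integer(nxt))
}

#' Filter the centerline cloud to the outer shell (PC2)
#'
#' Retains exactly the PC1 points whose containing voxel is labelled SHELL.
#' Infill points and inner perimeters fall in INTERIOR voxels and are
#' removed; numerical strays in EMPTY voxels are removed with a warning.
#' Chain links are re-threaded across removed points within the same
#' contiguous path.
#'
#' @param pc1 a \code{StagedPointCloud} at stage PC1
#' @param map a classified \code{VoxelLabelMap}
#' @return a \code{StagedPointCloud} at stage PC2
#' @export
shellFilter <- function(pc1, map) {
  if (pc1@stage != "PC1") stop("shellFilter expects a PC1 cloud")
  if (!map@classified) stop("label map must be classified first")
  lab <- voxelLabelAt(map, pc1@coords)
  keep <- lab == 2L
  nEmpty <- sum(lab == 0L)
  if (nEmpty > 0)
    warning(nEmpty, " point(s) fell in EMPTY voxels and were removed")
  if (!any(keep)) stop("empty shell: no points lie in SHELL voxels")
  lk <- .rethreadLinks(pc1@pathId[keep])
  .newCloud(pc1@coords[keep, , drop = FALSE], lk$prv, lk$nxt,
            pc1@layerIndex[keep], pc1@pathId[keep],
            pc1@tangent[keep, , drop = FALSE], pc1@feature[keep],
            stage = "PC2", role = pc1@role,
            diagnostics = c(pc1@diagnostics,
                            list(shellDroppedInterior = sum(lab == 1L),
                                 shellDroppedEmpty = nEmpty)))
}

#' XY nozzle-radius offset correction (PC3)
#'
#' For each shell point \eqn{P}, the two in-plane normals to the local
#' tangent give offset candidates \eqn{P' = P + v_1}, \eqn{P'' = P + v_2}
#' with \eqn{|v_1| = |v_2| = w/2}, at the same Z as \eqn{P}. The infill test
#' on the voxel label map decides:
#' one candidate inside the infill -> keep the other (the true surface);
#' neither inside -> keep both (free-standing single line);
#' both inside -> keep none and count an error-drop diagnostic.
#'
#' When both candidates are kept, the chain (used later for contour
#' reconstruction) follows the candidate that lies in an EMPTY voxel -- the
#' outermost filament boundary -- and the other candidate is carried
#' off-chain.
#'
#' @param pc2 a \code{StagedPointCloud} at stage PC2
#' @param map a classified \code{VoxelLabelMap}
#' @param w line width (mm); the offset magnitude is \code{w/2}
#' @return a \code{StagedPointCloud} at stage PC3
#' @export
xyCorrect <- function(pc2, map, w) {
  if (pc2@stage != "PC2") stop("xyCorrect expects a PC2 cloud")
  stopifnot(w > 0)
  p <- pc2@coords
  tg <- pc2@tangent
  usable <- !is.na(tg[, 1]) & !is.na(tg[, 2])
  nSkipped <- sum(!usable)
  if (nSkipped)
    warning(nSkipped, " point(s) without a usable tangent were skipped")
  # in-plane normals +/- (w/2) * (-ty, tx)
  nx <- -tg[, 2] * (w / 2)
  ny <- tg[, 1] * (w / 2)
  c1 <- cbind(p[, 1] + nx, p[, 2] + ny, p[, 3])
  c2 <- cbind(p[, 1] - nx, p[, 2] - ny, p[, 3])
  lab1 <- voxelLabelAt(map, c1)
  lab2 <- voxelLabelAt(map, c2)
  in1 <- lab1 == 1L
  in2 <- lab2 == 1L
  keep1 <- usable & !in1 & in2
  keep2 <- usable & in1 & !in2
  keepB <- usable & !in1 & !in2
  errDrop <- usable & in1 & in2

  # chain points: one output per surviving base point, in original order
  chainKeep <- keep1 | keep2 | keepB
  chainPt <- matrix(NA_real_, sum(chainKeep), 3)
  src <- which(chainKeep)
  useC1 <- keep1[src] | (keepB[src] & (lab1[src] == 0L | lab2[src] != 0L))
  chainPt[useC1, ] <- c1[src[useC1], , drop = FALSE]
  chainPt[!useC1, ] <- c2[src[!useC1], , drop = FALSE]
  lk <- .rethreadLinks(pc2@pathId[src])
  # off-chain partners of "single line" points
  extraSrc <- which(keepB)
  extraPt <- matrix(NA_real_, length(extraSrc), 3)
  useC1e <- keepB[extraSrc] & (lab1[extraSrc] == 0L | lab2[extraSrc] != 0L)
  # partner is the opposite of the chain representative
  extraPt[useC1e, ] <- c2[extraSrc[useC1e], , drop = FALSE]
  extraPt[!useC1e, ] <- c1[extraSrc[!useC1e], , drop = FALSE]

  coords <- rbind(chainPt, extraPt)
  nC <- nrow(chainPt); nE <- nrow(extraPt)
  prv <- c(lk$prv, rep(NA_integer_, nE))
  nxt <- c(lk$nxt, rep(NA_integer_, nE))
  .newCloud(coords, prv, nxt,
            c(pc2@layerIndex[src], pc2@layerIndex[extraSrc]),
            c(pc2@pathId[src], rep(NA_integer_, nE)),
            rbind(tg[src, , drop = FALSE], tg[extraSrc, , drop = FALSE]),
            c(pc2@feature[src], pc2@feature[extraSrc]),
            stage = "PC3", role = pc2@role,
            diagnostics = c(pc2@diagnostics,
                            list(xyErrorDrop = sum(errDrop),
                                 xyNoTangent = nSkipped,
                                 xySingleLine = sum(keepB),
                                 xyBaseCoords = unname(rbind(
                                   p[src, , drop = FALSE],
                                   p[extraSrc, , drop = FALSE])))))
}

#' Z deposition-plane correction (PC4)
#'
#' The nozzle Z in G-code is the top of the deposited layer; every point is
#' first moved down by the layer height \eqn{h}. A point is classified as
#' part of the superior edge -- and moved back up by \eqn{h}, so top
#' surfaces stay at the printed height -- when the voxel directly above its
#' deposition voxel is EMPTY (neither infill nor shell). The lookup uses
#' the point's pre-correction nozzle-centerline position (carried through
#' the XY stage), which lies inside the voxelized solid; the corrected
#' position itself sits half a line width outside the crust and would
#' classify every wall point as a top edge.
#'
#' @param pc3 a \code{StagedPointCloud} at stage PC3
#' @param map a classified \code{VoxelLabelMap}
#' @param h layer height (mm)
#' @return a \code{StagedPointCloud} at stage PC4
#' @export
zCorrect <- function(pc3, map, h) {
  if (pc3@stage != "PC3") stop("zCorrect expects a PC3 cloud")
  stopifnot(h > 0)
  p <- pc3@coords
  base <- pc3@diagnostics$xyBaseCoords
  if (is.null(base) || nrow(base) != nrow(p)) base <- p
  above <- cbind(base[, 1], base[, 2], base[, 3] + map@voxelSize)
  labAbove <- voxelLabelAt(map, above)
  superior <- labAbove == 0L
  z <- p[, 3] - h
  z[superior] <- z[superior] + h
  below <- z < map@origin[3]
  if (any(below)) {
    warning(sum(below), " point(s) shifted below the grid floor were clamped")
    z[below] <- map@origin[3]
  }
  .newCloud(cbind(p[, 1], p[, 2], z), pc3@prevIdx, pc3@nextIdx,
            pc3@layerIndex, pc3@pathId, pc3@tangent, pc3@feature,
            stage = "PC4", role = pc3@role,
            diagnostics = c(pc3@diagnostics,
                            list(zSuperiorEdge = sum(superior),
                                 zClamped = sum(below))))
}
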