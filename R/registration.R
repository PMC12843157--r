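#' Construct a rigid transform
#' @param rotation 3 x 3 rotation matrix (det +1)
#' @param translation length-3 numeric (mm)
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Rotation about the Z axis
#' @param deg angle in degrees
#' @param translation optional translation
#' @export
rotationZ <- function(deg, translation = c(0, 0, 0)) {
  a <- deg * pi / 180
  rigidTransform(matrix(c(cos(a), sin(a), 0,
                          -sin(a), cos(a), 0,
                          0, 0, 1), 3, 3), translation)
}

#' Compose rigid transforms (apply \code{b} first, then \code{a})
#' @param a,b \code{RigidTransform}s
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a rigid transform
#' @param t a \code{RigidTransform}
#' @export
invertTransform <- function(t) {
  rigidTransform(t(t@rotation), as.numeric(-t(t@rotation) %*% t@translation))
}

#' Rotation angle of a rigid transform (degrees)
#' @param t a \code{RigidTransform}
#' @export
rotationAngle <- function(t) {
  acos(pmin(1, pmax(-1, (sum(diag(t@rotation)) - 1) / 2))) * 180 / pi
}

# volumetric centroid of a watertight mesh (signed-tetra weighting)
.meshCentroid <- function(mesh) {
  mesh <- orientMesh(mesh)
  V <- mesh@vertices
  F <- mesh@faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c_ <- V[F[, 3], , drop = FALSE]
  vol6 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  ctr <- (a + b + c_) / 4
  colSums(ctr * vol6) / sum(vol6)
}

# Rotation-invariant bounding dimensions of a component: minimum-area
# enclosing rectangle of the XY footprint (rotating calipers over the convex
# hull) plus the Z extent. Scene placements rotate about Z (parts lie on the
# bed), so this recovers the object-frame bounding box.
.componentExtents <- function(p) {
  xy <- p[, 1:2, drop = FALSE]
  hull <- xy[grDevices::chull(xy), , drop = FALSE]
  n <- nrow(hull)
  best <- c(Inf, Inf, Inf)
  for (i in seq_len(n)) {
    e <- hull[if (i == n) 1 else i + 1, ] - hull[i, ]
    L <- sqrt(sum(e^2))
    if (L < 1e-12) next
    u <- e / L
    v <- c(-u[2], u[1])
    a <- hull %*% cbind(u, v)
    dx <- diff(range(a[, 1])); dy <- diff(range(a[, 2]))
    if (dx * dy < best[1]) best <- c(dx * dy, dx, dy)
  }
  c(best[2], best[3], diff(range(p[, 3])))
}

#' Split the corrected cloud into calibration object and model
#'
#' Finds the two 26-connected occupied components of the voxel map, assigns
#' every point to a component through a spatial-index lookup (nearest
#' occupied voxel), and identifies the calibration object as the component
#' whose rotation-invariant bounding dimensions (minimum-area enclosing
#' rectangle of the footprint plus Z extent) match the known calibration
#' dimensions (sorted comparison, tolerance per axis).
#'
#' @param pc a \code{StagedPointCloud} (typically PC4)
#' @param map the classified \code{VoxelLabelMap}
#' @param coDims calibration-object bounding dimensions (mm)
#' @param tol per-axis matching tolerance (mm)
#' @return list with elements \code{pco} (role CALIBRATION) and \code{pcm}
#'   (role MODEL)
#' @export
splitCalibration <- function(pc, map, coDims = c(10, 6.25, 8.75), tol = 0.5) {
  occ <- as.raw(as.integer(map@labels != .L_EMPTY))
  comp <- cpp_components(occ, map@dims)
  ncomp <- attr(comp, "n_components")
  if (ncomp != 2)
    stop("scene split error: expected exactly 2 connected components, found ",
         ncomp)
  ptComp <- cpp_point_component(comp, map@dims, map@origin, map@voxelSize,
                                pc@coords, 10L)
  if (any(ptComp == 0))
    stop("scene split error: ", sum(ptComp == 0),
         " point(s) could not be assigned to a component")
  target <- sort(coDims)
  isCO <- vapply(1:2, function(k) {
    ext <- sort(.componentExtents(pc@coords[ptComp == k, , drop = FALSE]))
    all(abs(ext - target) <= tol)
  }, logical(1))
  if (sum(isCO) != 1)
    stop("calibration object not found: ",
         if (sum(isCO) == 0) "no component matches its dimensions"
         else "both components match its dimensions")
  coK <- which(isCO)
  subCloud <- function(keep, role) {
    pid <- pc@pathId[keep]
    # off-chain points (NA pathId) each form their own degenerate path so the
    # re-threading never bridges through them
    pidEff <- pid
    off <- is.na(pidEff)
    pidEff[off] <- -seq_len(sum(off))
    lk <- .rethreadLinks(pidEff)
    lk$prv[off] <- NA_integer_
    lk$nxt[off] <- NA_integer_
    .newCloud(pc@coords[keep, , drop = FALSE], lk$prv, lk$nxt,
              pc@layerIndex[keep], pid,
              pc@tangent[keep, , drop = FALSE], pc@feature[keep],
              stage = pc@stage, role = role, diagnostics = pc@diagnostics)
  }
  list(pco = subCloud(ptComp == coK, "CALIBRATION"),
       pcm = subCloud(ptComp != coK, "MODEL"))
}

#' Center-of-mass pre-alignment
#'
#' Translation-only transform moving the unweighted mean of the corrected
#' calibration cloud onto the volumetric centroid of the reference
#' calibration mesh.
#'
#' @param pco calibration-object \code{StagedPointCloud}
#' @param coMesh reference calibration \code{TriangleMesh} (watertight)
#' @return a translation-only \code{RigidTransform}
#' @export
comPrealign <- function(pco, coMesh) {
  if (!nPoints(pco)) stop("empty calibration cloud")
  rigidTransform(diag(3), .meshCentroid(coMesh) - colMeans(pco@coords))
}

#' Rigid ICP refinement onto the calibration mesh
#'
#' Iterates nearest-point-on-surface correspondences and least-squares rigid
#' updates (SVD/Kabsch), starting from \code{init}. Converges when the RMS
#' residual falls below \code{conv} (0.02 mm), otherwise runs the full
#' \code{maxIter} iterations; declares failure if the residual increases for
#' five consecutive iterations. A corrected toolpath cloud carries
#' quantization scatter above \code{conv}, so in practice the iteration cap
#' governs and the update is iterated to numerical stationarity. No scaling,
#' no outlier trimming; correspondence ties are broken by lowest triangle
#' index, so the result is deterministic.
#'
#' @param pco calibration-object cloud
#' @param coMesh reference calibration mesh
#' @param init initial \code{RigidTransform} (e.g. from
#'   \code{\link{comPrealign}})
#' @param maxIter iteration cap (default 50)
#' @param conv convergence threshold on the RMS residual change (mm)
#' @return the composed \code{RigidTransform}; attribute \code{"icp"} holds
#'   the residual log, final RMS and iteration count
#' @export
icpRefine <- function(pco, coMesh, init = rigidTransform(),
                      maxIter = 50, conv = 0.02) {
  p0 <- pco@coords
  cur <- init
  rmsLog <- numeric(0)
  nUp <- 0L
  prevRms <- Inf
  for (it in seq_len(maxIter)) {
    p <- sweep(p0 %*% t(cur@rotation), 2, cur@translation, "+")
    res <- cpp_mesh_distance(coMesh@vertices, coMesh@faces, p, 1L)
    q <- res$closest
    rms <- sqrt(mean(res$distance^2))
    rmsLog <- c(rmsLog, rms)
    if (rms > prevRms + 1e-12) {
      nUp <- nUp + 1L
      if (nUp >= 5L) stop("registration failure: ICP residual diverged")
    } else nUp <- 0L
    if (rms < conv) break
    prevRms <- rms
    # least-squares rigid update p -> q (Kabsch)
    pm <- colMeans(p); qm <- colMeans(q)
    H <- crossprod(sweep(p, 2, pm), sweep(q, 2, qm))
    s <- svd(H)
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    tr <- qm - as.numeric(R %*% pm)
    cur <- composeTransforms(rigidTransform(R, tr), cur)
  }
  out <- cur
  attr(out, "icp") <- list(rms = rmsLog[length(rmsLog)], iterations = it,
                           residuals = rmsLog)
  out
}

#' Apply a rigid transform to a staged cloud
#'
#' Maps every point \eqn{x \mapsto R x + t}; links, stage and layer indices
#' are preserved; the role becomes \code{TPCM} (transformed point cloud,
#' model).
#'
#' @param pc a \code{StagedPointCloud}
#' @param t a \code{RigidTransform}
#' @param role role tag of the result (default \code{"TPCM"})
#' @export
applyTransform <- function(pc, t, role = "TPCM") {
  coords <- sweep(pc@coords %*% t(t@rotation), 2, t@translation, "+")
  tg <- pc@tangent
  ok <- !is.na(tg[, 1])
  if (any(ok)) {
    t3 <- cbind(tg[ok, 1, drop = FALSE], tg[ok, 2, drop = FALSE], 0) %*%
      t(t@rotation)
    L <- sqrt(t3[, 1]^2 + t3[, 2]^2)
    L[L == 0] <- 1
    tg[ok, ] <- t3[, 1:2] / L
  }
  .newCloud(coords, pc@prevIdx, pc@nextIdx, pc@layerIndex, pc@pathId,
            tg, pc@feature, stage = pc@stage, role = role,
            diagnostics = pc@diagnostics)
}

#' Serialize a rigid transform as a homogeneous 4 x 4 matrix (JSON)
#' @param t a \code{RigidTransform}
#' @param path optional output file
#' @export
transformToJSON <- function(t, path = NULL) {
  m <- rbind(cbind(t@rotation, t@translation), c(0, 0, 0, 1))
  js <- jsonlite::toJSON(list(matrix_row_major = as.vector(t(m))),
                         digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) writeLines(js, path)
  js
}
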