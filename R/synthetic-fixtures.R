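#' Extrude a simple CCW polygon into a watertight prism mesh
#'
#' @param poly n x 2 CCW polygon (mm)
#' @param z0,z1 bottom/top (mm)
#' @export
extrudedPolygonMesh <- function(poly, z0, z1) {
  stopifnot(z1 > z0)
  if (.polyArea(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  .prismMesh(poly, z0, z1)
}

#' Axis-aligned box mesh
#' @param dims c(dx, dy, dz) mm
#' @param origin minimum corner
#' @export
boxMesh <- function(dims, origin = c(0, 0, 0)) {
  p <- rbind(c(0, 0), c(dims[1], 0), c(dims[1], dims[2]), c(0, dims[2]))
  m <- extrudedPolygonMesh(sweep(p, 2, origin[1:2], "+"),
                           origin[3], origin[3] + dims[3])
  m
}

#' L-shaped solid (an L footprint extruded in Z)
#' @param a outer extent (mm), both arms
#' @param t arm thickness (mm)
#' @param height extrusion height (mm)
#' @param origin minimum corner
#' @export
lBeamMesh <- function(a = 20, t = 8, height = 5, origin = c(0, 0, 0)) {
  p <- rbind(c(0, 0), c(a, 0), c(a, t), c(t, t), c(t, a), c(0, a))
  extrudedPolygonMesh(sweep(p, 2, origin[1:2], "+"),
                      origin[3], origin[3] + height)
}

#' Regular n-gon prism (cylinder approximation)
#' @param radius circumradius (mm)
#' @param n number of sides
#' @param height extrusion height (mm)
#' @param center xy center
#' @export
ngonPrismMesh <- function(radius, n = 64, height = 5, center = c(0, 0)) {
  a <- 2 * pi * (seq_len(n) - 1) / n
  p <- cbind(center[1] + radius * cos(a), center[2] + radius * sin(a))
  extrudedPolygonMesh(p, 0, height)
}

#' The step-shaped calibration object
#'
#' Two orthogonal rectangular blocks forming a step, overall bounding box
#' exactly 10.00 x 6.25 x 8.75 mm (X x Y x Z), with three mutually
#' perpendicular reference faces on the coordinate planes. The asymmetric
#' step profile pins the orientation during rigid registration.
#'
#' @return a watertight \code{TriangleMesh}
#' @export
makeCalibrationObject <- function() {
  # step profile in the XZ plane: full-width base block up to z = 4, half-
  # width tower (x in [0, 5]) up to z = 8.75
  prof <- rbind(c(0, 0), c(10, 0), c(10, 4), c(5, 4), c(5, 8.75), c(0, 8.75))
  m <- extrudedPolygonMesh(prof, 0, 6.25)
  V <- m@vertices[, c(1, 3, 2)]             # profile-Y becomes world Z
  TriangleMesh(V, m@faces[, c(1, 3, 2)])    # axis swap mirrors; flip winding
}

# ---- planar mesh cross-section ---------------------------------------------

# closed polygons of the cross-section of a watertight mesh at height z
.meshCrossSection <- function(mesh, z) {
  V <- mesh@vertices
  F <- mesh@faces
  if (any(abs(V[, 3] - z) < 1e-9)) z <- z + 1e-6
  z1 <- V[F[, 1], 3]; z2 <- V[F[, 2], 3]; z3 <- V[F[, 3], 3]
  crossing <- (pmin(z1, z2, z3) < z) & (pmax(z1, z2, z3) > z)
  segs <- list()
  for (f in which(crossing)) {
    vv <- V[F[f, ], , drop = FALSE]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      za <- vv[e[1], 3]; zb <- vv[e[2], 3]
      if ((za < z) != (zb < z)) {
        t <- (z - za) / (zb - za)
        pts[[length(pts) + 1L]] <- vv[e[1], 1:2] + t * (vv[e[2], 1:2] -
                                                          vv[e[1], 1:2])
      }
    }
    if (length(pts) == 2)
      segs[[length(segs) + 1L]] <- rbind(pts[[1]], pts[[2]])
  }
  if (!length(segs)) return(list())
  key <- function(p) paste(round(p[1] * 1e6), round(p[2] * 1e6))
  ends <- lapply(segs, function(s) c(key(s[1, ]), key(s[2, ])))
  adj <- new.env()
  for (i in seq_along(segs))
    for (k in ends[[i]])
      assign(k, c(if (exists(k, adj)) get(k, adj), i), adj)
  usedSeg <- logical(length(segs))
  polys <- list()
  for (s0 in seq_along(segs)) {
    if (usedSeg[s0]) next
    loop <- segs[[s0]][1, , drop = FALSE]
    curKey <- ends[[s0]][1]
    nextKey <- ends[[s0]][2]
    usedSeg[s0] <- TRUE
    pt <- segs[[s0]][2, ]
    repeat {
      loop <- rbind(loop, pt)
      if (nextKey == ends[[s0]][1]) break
      cand <- Filter(function(i) !usedSeg[i], get(nextKey, adj))
      if (!length(cand)) break
      i <- cand[1]
      usedSeg[i] <- TRUE
      if (ends[[i]][1] == nextKey) {
        pt <- segs[[i]][2, ]; nextKey <- ends[[i]][2]
      } else {
        pt <- segs[[i]][1, ]; nextKey <- ends[[i]][1]
      }
    }
    loop <- .dropConsecutiveDupes(loop, closed = TRUE, tol = 1e-7)
    loop <- .dropCollinear(loop, tol = 1e-7)
    if (nrow(loop) >= 3) polys[[length(polys) + 1L]] <- loop
  }
  # orient even-odd: outers CCW, holes CW
  if (length(polys) > 1) {
    depth <- vapply(seq_along(polys), function(i)
      sum(vapply(seq_along(polys), function(j)
        j != i && .pointInPoly(polys[[i]][1, ], polys[[j]]), logical(1))),
      integer(1))
  } else depth <- rep(0L, length(polys))
  for (i in seq_along(polys)) {
    wantCCW <- depth[i] %% 2 == 0
    if ((.polyArea(polys[[i]]) > 0) != wantCCW)
      polys[[i]] <- polys[[i]][rev(seq_len(nrow(polys[[i]]))), , drop = FALSE]
  }
  polys
}

# mitered inward offset of a simple CCW polygon; NULL when it vanishes
.polygonInset <- function(poly, d) {
  n <- nrow(poly)
  inx <- c(2:n, 1)
  e <- poly[inx, ] - poly
  L <- sqrt(rowSums(e^2))
  keep <- L > 1e-12
  poly <- poly[keep, , drop = FALSE]
  n <- nrow(poly)
  if (n < 3) return(NULL)
  inx <- c(2:n, 1)
  ip <- c(n, seq_len(n - 1))
  e <- poly[inx, ] - poly
  L <- sqrt(rowSums(e^2))
  nrm <- cbind(-e[, 2], e[, 1]) / L   # inward normal of a CCW polygon
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    # intersect offset lines of edges (i-1) and i
    a1 <- poly[ip[i], ] + d * nrm[ip[i], ]; d1 <- e[ip[i], ]
    a2 <- poly[i, ] + d * nrm[i, ];         d2 <- e[i, ]
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-9) {
      out[i, ] <- poly[i, ] + d * nrm[i, ]
    } else {
      t <- ((a2[1] - a1[1]) * d2[2] - (a2[2] - a1[2]) * d2[1]) / den
      out[i, ] <- a1 + t * d1
    }
  }
  out <- .dropConsecutiveDupes(out, closed = TRUE)
  if (nrow(out) < 3 || .polyArea(out) <= 0) return(NULL)
  out
}

# rectilinear hatch segments of a polygon: lines parallel to X (angle 0) or
# Y (angle 90) at the given spacing, anchored to the polygon's own bounding
# box so the pattern translates with the object
.rectilinearHatch <- function(poly, spacing, angle) {
  p <- if (angle == 0) poly else poly[, c(2, 1)]
  ymin <- min(p[, 2]); ymax <- max(p[, 2])
  nl <- floor((ymax - ymin) / spacing - 0.5) + 1L
  if (nl < 1) return(list())
  ys <- ymin + (seq_len(nl) - 0.5) * spacing
  n <- nrow(p)
  inx <- c(2:n, 1)
  segs <- list()
  flip <- FALSE
  for (yc in ys) {
    y1 <- p[, 2]; y2 <- p[inx, 2]
    hit <- (y1 > yc) != (y2 > yc)
    if (!any(hit)) next
    xs <- p[hit, 1] + (yc - y1[hit]) * (p[inx, 1][hit] - p[hit, 1]) /
      (y2[hit] - y1[hit])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      a <- c(xs[k], yc); b <- c(xs[k + 1], yc)
      if (flip) { tmp <- a; a <- b; b <- tmp }
      s <- rbind(a, b)
      if (angle != 0) s <- s[, c(2, 1)]
      segs[[length(segs) + 1L]] <- s
    }
    flip <- !flip
  }
  segs
}

#' Compose a synthetic fixture scene
#'
#' Places the step calibration object near the global origin, the model
#' beside it with the given clearance, and applies a rigid placement to both
#' (simulating the slicer's unknown coordinate system). The unplaced meshes
#' are kept as the ground-truth reference.
#'
#' @param model a watertight \code{TriangleMesh} (any position; it is moved
#'   next to the calibration object)
#' @param placement ground-truth \code{RigidTransform} applied to the scene
#' @param seed integer recorded in the slicing parameters
#' @param clearance gap between calibration object and model (mm)
#' @param h,w,nPerimeters,infillOverlap slicing parameters
#' @return a \code{\linkS4class{FixtureScene}}
#' @export
composeScene <- function(model, placement = rigidTransform(), seed = 1L,
                         clearance = 5, h = 0.2, w = 0.4, nPerimeters = 2,
                         infillOverlap = 0.55) {
  co <- makeCalibrationObject()
  cmax <- apply(co@vertices, 2, max)
  mmin <- apply(model@vertices, 2, min)
  shift <- c(cmax[1] + clearance - mmin[1], -mmin[2], -mmin[3])
  modelRef <- TriangleMesh(sweep(model@vertices, 2, shift, "+"), model@faces)
  if (clearance < 2)
    stop("model collides with the calibration object (clearance < 2 mm)")
  new("FixtureScene",
      modelMesh = transformMesh(modelRef, placement),
      coMesh = transformMesh(co, placement),
      modelRef = modelRef, coRef = co, placement = placement,
      slicingParams = list(h = h, w = w, nPerimeters = nPerimeters,
                           infillOverlap = infillOverlap, seed = seed))
}

#' Deterministic mini-slicer
#'
#' Emits RepRap-style G-code for a fixture scene: per layer (cross-sections
#' at mid-layer height, nozzle Z at the layer top), two inset perimeters at
#' offsets w/2 and 3w/2 from the surface, and 100% rectilinear infill at
#' spacing w alternating 0/90 degrees per layer, with absolute-E extrusion
#' proportional to path length x w x h, retraction between layers, a
#' deterministic seam (lexicographically smallest vertex), and header
#' comments carrying the layer height and line width. A final partial layer
#' (height not divisible by h) is omitted.
#'
#' @param scene a \code{FixtureScene}
#' @return character vector of G-code lines
#' @export
miniSlice <- function(scene) {
  sp <- scene@slicingParams
  h <- sp$h; w <- sp$w
  filArea <- pi * (1.75 / 2)^2
  eRate <- w * h / filArea   # mm filament per mm path
  meshes <- list(co = scene@coMesh, model = scene@modelMesh)
  heights <- vapply(meshes, function(m) max(m@vertices[, 3]), numeric(1))
  zmins <- vapply(meshes, function(m) min(m@vertices[, 3]), numeric(1))
  nLayers <- floor((heights - min(zmins)) / h + 1e-9)
  out <- c("; slicerQC mini-slicer",
           sprintf("; layer_height = %g", h),
           sprintf("; line_width = %g", w),
           "; extrusion_multiplier = 1",
           "G90", "M82", "G92 E0")
  e <- 0
  fmt <- function(x) sprintf("%.5f", x)
  fmtE <- function(x) sprintf("%.6f", x)
  emitLoop <- function(loop, type) {
    # seam at the lexicographically smallest vertex (rounded keys so the
    # choice is stable under exact scene translations)
    i0 <- order(round(loop[, 1], 4), round(loop[, 2], 4))[1]
    loop <- loop[c(i0:nrow(loop), seq_len(i0 - 1)), , drop = FALSE]
    loop <- rbind(loop, loop[1, ])
    lines <- c(sprintf(";TYPE:%s", type),
               sprintf("G0 X%s Y%s F7800", fmt(loop[1, 1]), fmt(loop[1, 2])))
    for (i in 2:nrow(loop)) {
      len <- sqrt(sum((loop[i, ] - loop[i - 1, ])^2))
      e <<- e + len * eRate
      lines <- c(lines, sprintf("G1 X%s Y%s E%s F4800",
                                fmt(loop[i, 1]), fmt(loop[i, 2]), fmtE(e)))
    }
    lines
  }
  emitSeg <- function(s, type) {
    len <- sqrt(sum((s[2, ] - s[1, ])^2))
    l1 <- sprintf("G0 X%s Y%s F7800", fmt(s[1, 1]), fmt(s[1, 2]))
    e <<- e + len * eRate
    c(sprintf(";TYPE:%s", type),
      l1, sprintf("G1 X%s Y%s E%s F4800", fmt(s[2, 1]), fmt(s[2, 2]), fmtE(e)))
  }
  maxL <- max(nLayers)
  for (k in seq_len(maxL) - 1L) {
    zCut <- (k + 0.5) * h
    zNozzle <- (k + 1) * h
    eStart <- e
    layerLines <- character(0)
    for (mi in seq_along(meshes)) {
      if (k + 1 > nLayers[mi]) next
      polys <- .meshCrossSection(meshes[[mi]], zCut)
      for (poly in polys) {
        if (.polyArea(poly) < 0) next  # fixture solids have no holes
        for (pi in seq_len(sp$nPerimeters)) {
          off <- w / 2 + (pi - 1) * w
          loop <- .polygonInset(poly, off)
          if (is.null(loop)) next
          layerLines <- c(layerLines,
                          emitLoop(loop, if (pi == 1) "WALL-OUTER"
                                   else "WALL-INNER"))
        }
        infOff <- w / 2 + (sp$nPerimeters - 1) * w + w * (1 - sp$infillOverlap)
        region <- .polygonInset(poly, infOff)
        if (!is.null(region)) {
          angle <- if (k %% 2 == 0) 0 else 90
          for (s in .rectilinearHatch(region, w, angle))
            layerLines <- c(layerLines, emitSeg(s, "FILL"))
        }
      }
    }
    if (length(layerLines)) {
      out <- c(out,
               sprintf("; layer %d", k),
               sprintf("G1 Z%s F9000", fmt(zNozzle)),
               sprintf("G1 E%s F2400", fmtE(eStart)),  # un-retract
               layerLines,
               sprintf("G1 E%s F2400", fmtE(e - 0.8))) # retract
    }
  }
  out
}

#' Sample rigid scene placements
#'
#' Translations on the voxel grid (multiples of \code{gridStep}) up to
#' \code{maxTranslation} in X and Y (Z stays 0, as on a printer bed), and
#' rotations about Z up to \code{maxRotationDeg}.
#'
#' @param n number of placements
#' @param seed RNG seed
#' @param maxTranslation mm
#' @param maxRotationDeg degrees
#' @param gridStep translation granularity (mm)
#' @return list of \code{RigidTransform}
#' @export
samplePlacements <- function(n, seed = 1L, maxTranslation = 150,
                             maxRotationDeg = 5, gridStep = 0.1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tx <- round(stats::runif(1, -maxTranslation, maxTranslation) / gridStep) *
      gridStep
    ty <- round(stats::runif(1, -maxTranslation, maxTranslation) / gridStep) *
      gridStep
    th <- stats::runif(1, -maxRotationDeg, maxRotationDeg)
    rotationZ(th, c(tx, ty, 0))
  })
}
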