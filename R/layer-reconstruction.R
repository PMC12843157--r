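# ---- 2D polygon helpers ----------------------------------------------------

.polyArea <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

.pointInPoly <- function(pt, poly) {
  # even-odd rule
  n <- nrow(poly)
  j <- c(n, seq_len(n - 1))
  xi <- poly[, 1]; yi <- poly[, 2]
  xj <- poly[j, 1]; yj <- poly[j, 2]
  cross <- ((yi > pt[2]) != (yj > pt[2])) &
    (pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi)
  sum(cross) %% 2 == 1
}

.snapGrid <- function(p, grid = 1e-3) round(p / grid) * grid

.dropConsecutiveDupes <- function(p, closed = TRUE, tol = 1e-9) {
  n <- nrow(p)
  if (n < 2) return(p)
  prev <- p[c(n, seq_len(n - 1)), , drop = FALSE]
  d <- sqrt(rowSums((p - prev)^2))
  keep <- d > tol
  if (!closed) keep[1] <- TRUE
  p[keep, , drop = FALSE]
}

# Remove vertices whose perpendicular distance to the chord of their
# neighbours is below tol (mm). The tolerance sits just above the 1 um
# snap-rounding noise so straight runs collapse to their endpoints even on
# rotated walls.
.dropCollinear <- function(p, tol = 2e-3) {
  repeat {
    n <- nrow(p)
    if (n < 4) return(p)
    ip <- c(n, seq_len(n - 1))
    inx <- c(2:n, 1)
    v1 <- p - p[ip, , drop = FALSE]
    v2 <- p[inx, , drop = FALSE] - p
    ch <- p[inx, , drop = FALSE] - p[ip, , drop = FALSE]
    cr <- abs(v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
    dt <- v1[, 1] * v2[, 1] + v1[, 2] * v2[, 2]
    chL <- pmax(sqrt(ch[, 1]^2 + ch[, 2]^2), 1e-12)
    drop <- (cr / chL) < tol & dt > 0
    if (!any(drop)) return(p)
    # never drop two adjacent vertices in one pass (keeps the bound local)
    dd <- drop & !c(FALSE, drop[-n])
    p <- p[!dd, , drop = FALSE]
  }
}

# Deterministic ear clipping of a simple CCW polygon; falls back to a fan for
# numerically degenerate remainders. Returns an index matrix into the input.
.earClip <- function(p) {
  n <- nrow(p)
  idx <- seq_len(n)
  tris <- matrix(0L, 0, 3)
  guard <- 0L
  while (length(idx) > 3) {
    m <- length(idx)
    found <- FALSE
    for (k in seq_len(m)) {
      a <- idx[if (k == 1) m else k - 1]
      b <- idx[k]
      c_ <- idx[if (k == m) 1 else k + 1]
      v1 <- p[b, ] - p[a, ]
      v2 <- p[c_, ] - p[b, ]
      if (v1[1] * v2[2] - v1[2] * v2[1] <= 1e-12) next # reflex or degenerate
      others <- setdiff(idx, c(a, b, c_))
      inside <- FALSE
      for (o in others) {
        # barycentric containment (closed)
        d0 <- p[c_, ] - p[a, ]; d1 <- p[b, ] - p[a, ]; d2 <- p[o, ] - p[a, ]
        den <- d0[1] * d1[2] - d1[1] * d0[2]
        if (abs(den) < 1e-15) next
        u <- (d2[1] * d1[2] - d1[1] * d2[2]) / den
        v <- (d0[1] * d2[2] - d2[1] * d0[2]) / den
        if (u >= -1e-12 && v >= -1e-12 && u + v <= 1 + 1e-12) {
          inside <- TRUE; break
        }
      }
      if (inside) next
      tris <- rbind(tris, c(a, b, c_))
      idx <- idx[-k]
      found <- TRUE
      break
    }
    if (!found) { # degenerate remainder: fan (signed volumes still correct)
      for (k in 2:(length(idx) - 1))
        tris <- rbind(tris, c(idx[1], idx[k], idx[k + 1]))
      idx <- idx[1:3]
      break
    }
    guard <- guard + 1L
    if (guard > n + 5L) break
  }
  if (length(idx) == 3) tris <- rbind(tris, idx)
  tris
}

# a point strictly inside a closed polygon (even-odd): the centroid when it
# is interior, else edge midpoints nudged sideways
.innerTestPoint <- function(poly, step) {
  ctr <- colMeans(poly)
  if (.pointInPoly(ctr, poly)) return(ctr)
  n <- nrow(poly)
  inx <- c(2:n, 1)
  for (i in seq_len(n)) {
    mid <- (poly[i, ] + poly[inx[i], ]) / 2
    e <- poly[inx[i], ] - poly[i, ]
    L <- sqrt(sum(e^2))
    if (L < 1e-9) next
    nrm <- c(-e[2], e[1]) / L
    for (s in c(step, -step)) {
      cand <- mid + s * nrm
      if (.pointInPoly(cand, poly)) return(cand)
    }
  }
  NULL
}

#' Trace closed layer contours from the corrected cloud
#'
#' Chains are followed through the G-code links within one layer; chains
#' whose endpoints coincide within \code{eps} close into polygons
#' (snap-rounded to a 1 um grid, consecutive duplicates and collinear
#' vertices removed). Nesting is resolved even-odd: outer contours are
#' oriented CCW, holes CW. Chains that fail to close are returned as
#' \code{openChains} diagnostics.
#'
#' On top and bottom layers the whole deposition plane lies in SHELL voxels,
#' so the XY correction keeps both candidates ("single line") for the inner
#' perimeter too, and its ring would nest as a spurious hole. When the voxel
#' label map is supplied, hole (CW) contours with deposited material inside
#' them are recognised as such inner rings and dropped; genuine holes have
#' empty space inside and are kept.
#'
#' @param pc4 a \code{StagedPointCloud} at stage PC4 with intact links
#' @param layer 0-based layer index
#' @param h layer height (mm)
#' @param eps closure tolerance (mm); default \code{w/4} with w = 0.40
#' @param map optional classified \code{VoxelLabelMap} for hole validation
#' @return a \code{\linkS4class{LayerContourSet}}
#' @export
buildLayerContours <- function(pc4, layer, h, eps = 0.1, map = NULL) {
  if (pc4@stage != "PC4") stop("buildLayerContours expects a PC4 cloud")
  sel <- which(pc4@layerIndex == layer)
  contours <- list()
  open <- list()
  if (length(sel)) {
    inLayer <- logical(nPoints(pc4))
    inLayer[sel] <- TRUE
    prv <- pc4@prevIdx; nxt <- pc4@nextIdx
    starts <- sel[is.na(prv[sel]) | !inLayer[pmax(prv[sel], 1L)]]
    visited <- logical(nPoints(pc4))
    for (s in starts) {
      if (visited[s]) next
      chain <- integer(0)
      i <- s
      while (!is.na(i) && inLayer[i] && !visited[i]) {
        visited[i] <- TRUE
        chain <- c(chain, i)
        i <- nxt[i]
      }
      if (length(chain) < 3) next
      xy <- pc4@coords[chain, 1:2, drop = FALSE]
      gap <- sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2))
      closed <- gap <= eps
      if (closed && gap < 1e-9) xy <- xy[-nrow(xy), , drop = FALSE]
      xy <- .snapGrid(xy)
      xy <- .dropConsecutiveDupes(xy, closed = closed)
      xy <- .dropCollinear(xy)
      if (closed && nrow(xy) >= 3 && abs(.polyArea(xy)) > 1e-9)
        contours[[length(contours) + 1L]] <- xy
      else open[[length(open) + 1L]] <- xy
    }
    if (length(contours) > 1) {
      depth <- vapply(seq_along(contours), function(i) {
        sum(vapply(seq_along(contours), function(j)
          j != i && .pointInPoly(contours[[i]][1, ], contours[[j]]),
          logical(1)))
      }, integer(1))
    } else depth <- rep(0L, length(contours))
    for (i in seq_along(contours)) {
      a <- .polyArea(contours[[i]])
      wantCCW <- depth[i] %% 2 == 0
      if ((a > 0) != wantCCW)
        contours[[i]] <- contours[[i]][rev(seq_len(nrow(contours[[i]]))), ,
                                       drop = FALSE]
    }
    if (!is.null(map) && length(contours)) {
      spurious <- vapply(seq_along(contours), function(i) {
        if (depth[i] %% 2 == 0) return(FALSE)  # outer contours always kept
        pt <- .innerTestPoint(contours[[i]], 3 * map@voxelSize)
        if (is.null(pt)) return(FALSE)
        # test at the layer's deposition plane (its own occupied voxel row)
        voxelLabelAt(map, cbind(pt[1], pt[2], (layer + 1) * h)) != 0L
      }, logical(1))
      contours <- contours[!spurious]
    }
  }
  new("LayerContourSet", layerIndex = as.integer(layer),
      zBottom = layer * h, zTop = (layer + 1) * h,
      contours = contours, openChains = open)
}

# watertight prism over one CCW polygon (flip = TRUE inverts orientation,
# used for holes so signed volumes subtract)
.prismMesh <- function(poly, z0, z1, flip = FALSE) {
  n <- nrow(poly)
  V <- rbind(cbind(poly, z0), cbind(poly, z1))
  i2 <- c(2:n, 1)
  side <- rbind(cbind(seq_len(n), i2, i2 + n),
                cbind(seq_len(n), i2 + n, seq_len(n) + n))
  capT <- .earClip(poly)
  Fc <- rbind(side,
              capT[, c(1, 3, 2), drop = FALSE],        # bottom, normal -z
              capT + n)                                 # top, normal +z
  if (flip) Fc <- Fc[, c(1, 3, 2), drop = FALSE]
  TriangleMesh(V, Fc)
}

#' Extrude a layer contour set into a watertight slab
#'
#' Prisms over every closed polygon between \code{zBottom} and \code{zTop}:
#' triangulated caps, vertical side walls. Holes (CW contours) contribute
#' inverted prisms so the signed slab volume equals net polygon area x h.
#' Zero-area polygons are skipped with a warning.
#'
#' @param cs a \code{LayerContourSet} with at least one closed polygon
#' @return a \code{TriangleMesh}
#' @export
extrudeLayer <- function(cs) {
  if (!length(cs@contours)) stop("no closed polygons in layer ", cs@layerIndex)
  parts <- list()
  for (poly in cs@contours) {
    a <- .polyArea(poly)
    if (abs(a) < 1e-9) { warning("zero-area polygon skipped"); next }
    hole <- a < 0
    pccw <- if (hole) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
    parts[[length(parts) + 1L]] <- .prismMesh(pccw, cs@zBottom, cs@zTop,
                                              flip = hole)
  }
  if (!length(parts)) stop("no usable polygons in layer ", cs@layerIndex)
  .concatMeshes(parts)
}

.concatMeshes <- function(meshes) {
  off <- 0L
  Vs <- list(); Fs <- list()
  for (m in meshes) {
    Vs[[length(Vs) + 1L]] <- m@vertices
    Fs[[length(Fs) + 1L]] <- m@faces + off
    off <- off + nrow(m@vertices)
  }
  TriangleMesh(do.call(rbind, Vs), do.call(rbind, Fs))
}

#' Merge extruded layer slabs into one mesh
#'
#' Slabs must occupy disjoint Z intervals. When two consecutive slabs meet
#' with identical cap triangulations, the coincident opposing interface
#' faces are cancelled and the slabs fuse into a continuous wall; where the
#' caps differ (staircase offsets, first/last layers with different
#' contours) both caps are retained and the slabs remain separate closed
#' components, so the result is always watertight. The signed volume is
#' exactly the sum of the slab volumes in either case.
#'
#' @param slabs list of \code{TriangleMesh}
#' @return a \code{TriangleMesh}
#' @export
mergeLayers <- function(slabs) {
  if (!length(slabs)) stop("no slabs to merge")
  if (length(slabs) == 1) return(slabs[[1]])
  zr <- t(vapply(slabs, function(m) range(m@vertices[, 3]), numeric(2)))
  o <- order(zr[, 1])
  if (any(zr[o[-1], 1] < zr[o[-length(o)], 2] - 1e-9))
    stop("slabs overlap in Z; layers must occupy disjoint slabs")
  slabs <- slabs[o]
  n <- length(slabs)
  info <- lapply(slabs, function(m) {
    V <- .snapGrid(m@vertices, 1e-6)
    vk <- paste(V[, 1], V[, 2], V[, 3], sep = "/")
    z <- V[, 3]
    zmin <- min(z); zmax <- max(z)
    fk <- function(f) paste(sort(vk[f]), collapse = "|")
    onTop <- apply(m@faces, 1, function(f) all(abs(z[f] - zmax) < 1e-9))
    onBot <- apply(m@faces, 1, function(f) all(abs(z[f] - zmin) < 1e-9))
    list(V = V, F = m@faces, vk = vk, zmin = zmin, zmax = zmax,
         topIdx = which(onTop), botIdx = which(onBot),
         topKeys = apply(m@faces[onTop, , drop = FALSE], 1, fk),
         botKeys = apply(m@faces[onBot, , drop = FALSE], 1, fk))
  })
  fused <- logical(n - 1)
  for (i in seq_len(n - 1)) {
    a <- info[[i]]; b <- info[[i + 1]]
    fused[i] <- abs(a$zmax - b$zmin) < 1e-9 &&
      length(a$topKeys) == length(b$botKeys) &&
      setequal(a$topKeys, b$botKeys)
  }
  group <- cumsum(c(1L, as.integer(!fused)))
  Vs <- list(); Fs <- list(); keys <- list()
  off <- 0L
  for (i in seq_len(n)) {
    a <- info[[i]]
    keep <- rep(TRUE, nrow(a$F))
    if (i > 1 && fused[i - 1]) keep[a$botIdx] <- FALSE
    if (i < n && fused[i]) keep[a$topIdx] <- FALSE
    Vs[[i]] <- a$V
    Fs[[i]] <- a$F[keep, , drop = FALSE] + off
    # vertices weld only within a fusion group: coincident geometry across
    # unfused interfaces stays topologically separate
    keys[[i]] <- paste(group[i], a$vk)
    off <- off + nrow(a$V)
  }
  V <- do.call(rbind, Vs)
  Fc <- do.call(rbind, Fs)
  vkey <- unlist(keys)
  vid <- match(vkey, vkey)
  tv <- matrix(vid[Fc], ncol = 3)
  used <- sort(unique(as.vector(tv)))
  remap <- match(seq_len(nrow(V)), used)
  TriangleMesh(V[used, , drop = FALSE], matrix(remap[tv], ncol = 3))
}

#' Reconstruct a watertight solid from the corrected cloud
#'
#' Builds per-layer contours from the G-code chain order, extrudes each
#' layer by the layer height, and merges the slabs. Layers without closed
#' contours are skipped and reported.
#'
#' @param pc a \code{StagedPointCloud} at stage PC4 (any role)
#' @param h layer height (mm)
#' @param eps contour closure tolerance (mm)
#' @param map optional classified \code{VoxelLabelMap} for hole validation
#'   (see \code{\link{buildLayerContours}})
#' @return list: \code{mesh} (\code{TriangleMesh}),
#'   \code{layers} (per-layer diagnostics data.frame)
#' @export
reconstructMesh <- function(pc, h, eps = 0.1, map = NULL) {
  lays <- sort(unique(pc@layerIndex))
  slabs <- list()
  diag <- data.frame(layer = integer(), n_polygons = integer(),
                     n_open_chains = integer(), area = numeric(),
                     volume = numeric())
  for (L in lays) {
    cs <- buildLayerContours(pc, L, h, eps, map = map)
    if (!length(cs@contours)) {
      diag <- rbind(diag, data.frame(layer = L, n_polygons = 0L,
                                     n_open_chains = length(cs@openChains),
                                     area = 0, volume = 0))
      next
    }
    slab <- extrudeLayer(cs)
    a <- sum(vapply(cs@contours, .polyArea, numeric(1)))
    slabs[[length(slabs) + 1L]] <- slab
    diag <- rbind(diag, data.frame(layer = L, n_polygons = length(cs@contours),
                                   n_open_chains = length(cs@openChains),
                                   area = a, volume = a * h))
  }
  if (!length(slabs)) stop("reconstruction failed: no layer produced contours")
  list(mesh = mergeLayers(slabs), layers = diag)
}
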