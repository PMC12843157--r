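# Shared fixtures, built once per test run. The box scene (20 x 20 x 2 mm
# model plus the step calibration object, identity placement) is the
# workhorse: small enough to pipeline in seconds, large enough to have real
# perimeters, infill, top/bottom skins and a registration problem.

.fixtureCache <- new.env(parent = emptyenv())

fixtureBoxScene <- function() {
  if (is.null(.fixtureCache$boxScene))
    .fixtureCache$boxScene <- composeScene(boxMesh(c(20, 20, 2)))
  .fixtureCache$boxScene
}

fixtureBoxGcode <- function() {
  if (is.null(.fixtureCache$boxGcode))
    .fixtureCache$boxGcode <- miniSlice(fixtureBoxScene())
  .fixtureCache$boxGcode
}

# full pipeline stages for the box scene (parsed once, reused by many tests)
fixtureBoxStages <- function() {
  if (is.null(.fixtureCache$boxStages)) {
    scene <- fixtureBoxScene()
    .fixtureCache$boxStages <- suppressWarnings(
      runCompare(fixtureBoxGcode(), scene@modelRef, scene@coRef,
                 stages = TRUE))
  }
  .fixtureCache$boxStages
}

# unit cube as an indexed mesh
fixtureUnitCube <- function() boxMesh(c(1, 1, 1))

# brute-force R oracle for signed point-to-mesh distance: exhaustive scan
# over triangles with closed-form closest-point evaluation, lowest-index
# tie-break, and the same angle-weighted pseudo-normal sign rule. Written
# independently of the compiled path (vectorised R).
oracleSignedDistance <- function(pts, mesh) {
  V <- meshVertices(mesh)
  F <- meshFaces(mesh)
  nf <- nrow(F)
  closestOnTri <- function(p, a, b, c) {
    ab <- b - a; ac <- c - a; ap <- p - a
    d1 <- sum(ab * ap); d2 <- sum(ac * ap)
    if (d1 <= 0 && d2 <= 0) return(list(q = a, region = "v1"))
    bp <- p - b
    d3 <- sum(ab * bp); d4 <- sum(ac * bp)
    if (d3 >= 0 && d4 <= d3) return(list(q = b, region = "v2"))
    vc <- d1 * d4 - d3 * d2
    if (vc <= 0 && d1 >= 0 && d3 <= 0)
      return(list(q = a + ab * d1 / (d1 - d3), region = "e12"))
    cp <- p - c
    d5 <- sum(ab * cp); d6 <- sum(ac * cp)
    if (d6 >= 0 && d5 <= d6) return(list(q = c, region = "v3"))
    vb <- d5 * d2 - d1 * d6
    if (vb <= 0 && d2 >= 0 && d6 <= 0)
      return(list(q = a + ac * d2 / (d2 - d6), region = "e13"))
    va <- d3 * d6 - d5 * d4
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
      return(list(q = b + (c - b) * (d4 - d3) / ((d4 - d3) + (d5 - d6)),
                  region = "e23"))
    den <- va + vb + vc
    list(q = a + ab * (vb / den) + ac * (vc / den), region = "f")
  }
  unitCross <- function(u, v) {
    n <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    n / sqrt(sum(n^2))
  }
  faceN <- t(apply(F, 1, function(f)
    unitCross(V[f[2], ] - V[f[1], ], V[f[3], ] - V[f[1], ])))
  angleAt <- function(f, vi) {
    others <- setdiff(F[f, ], vi)
    e1 <- V[others[1], ] - V[vi, ]; e2 <- V[others[2], ] - V[vi, ]
    acos(max(-1, min(1, sum(e1 * e2) /
                       sqrt(sum(e1^2) * sum(e2^2)))))
  }
  vertN <- function(vi) {
    inc <- which(apply(F, 1, function(f) vi %in% f))
    n <- colSums(faceN[inc, , drop = FALSE] *
                   vapply(inc, angleAt, numeric(1), vi = vi))
    n / sqrt(sum(n^2))
  }
  edgeN <- function(v1, v2) {
    inc <- which(apply(F, 1, function(f) v1 %in% f && v2 %in% f))
    n <- colSums(faceN[inc, , drop = FALSE])
    n / sqrt(sum(n^2))
  }
  apply(matrix(pts, ncol = 3), 1, function(p) {
    best <- NULL
    for (f in seq_len(nf)) {
      r <- closestOnTri(p, V[F[f, 1], ], V[F[f, 2], ], V[F[f, 3], ])
      d2 <- sum((p - r$q)^2)
      if (is.null(best) || d2 < best$d2) best <- c(r, list(d2 = d2, f = f))
    }
    d <- sqrt(best$d2)
    if (d == 0) return(0)
    nrm <- switch(best$region,
                  f = faceN[best$f, ],
                  v1 = vertN(F[best$f, 1]),
                  v2 = vertN(F[best$f, 2]),
                  v3 = vertN(F[best$f, 3]),
                  e12 = edgeN(F[best$f, 1], F[best$f, 2]),
                  e13 = edgeN(F[best$f, 1], F[best$f, 3]),
                  e23 = edgeN(F[best$f, 2], F[best$f, 3]))
    s <- sum((p - best$q) * nrm)
    if (s >= 0) d else -d
  })
}

# shoelace polygon area oracle
oraclePolyArea <- function(p) {
  n <- nrow(p)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2]
  }
  s / 2
}

# line-by-line cumulative-extrusion oracle for absolute-E G-code (tracks the
# retraction state machine independently of the parser)
oracleExtrusionTotal <- function(lines) {
  e <- 0; maxE <- 0; total <- 0
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (!grepl("^\\s*G1\\b", ln, ignore.case = TRUE)) next
    m <- regmatches(ln, regexpr("E-?[0-9.]+", ln))
    if (!length(m)) next
    enew <- as.numeric(sub("E", "", m))
    if (enew > maxE) total <- total + enew - max(e, maxE)
    e <- enew
    maxE <- max(maxE, enew)
  }
  total
}

# brute-force 6-connected exterior flood fill (BFS over array indices)
.slicerQCFloodOracle <- function(occ) {
  d <- dim(occ)
  ext <- array(FALSE, d)
  q <- which(!occ, arr.ind = TRUE)
  onB <- q[, 1] == 1 | q[, 1] == d[1] | q[, 2] == 1 | q[, 2] == d[2] |
    q[, 3] == 1 | q[, 3] == d[3]
  front <- q[onB, , drop = FALSE]
  ext[front] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  while (nrow(front)) {
    nxt <- NULL
    for (s in seq_len(6)) {
      cand <- sweep(front, 2, shifts[s, ], "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
        cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      isNew <- !ext[cand] & !occ[cand]
      cand <- cand[isNew, , drop = FALSE]
      if (nrow(cand)) { ext[cand] <- TRUE; nxt <- rbind(nxt, cand) }
    }
    front <- if (is.null(nxt)) matrix(0, 0, 3) else unique(nxt)
  }
  ext
}

# TRUE where a voxel has any 26-neighbour set in `mask` (array-shift dilation)
.slicerQCDilate26 <- function(mask) {
  d <- dim(mask)
  out <- array(FALSE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
    ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
    zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
    sh <- mask[xs, ys, zs]
    # clamped shifts replicate the border; mask them out where clamped
    if (dx != 0) sh[if (dx > 0) d[1] else 1, , ] <- FALSE
    if (dy != 0) sh[, if (dy > 0) d[2] else 1, ] <- FALSE
    if (dz != 0) sh[, , if (dz > 0) d[3] else 1] <- FALSE
    out <- out | sh
  }
  out
}
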