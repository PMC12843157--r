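.newCloud <- function(coords, prevIdx, nextIdx, layerIndex, pathId, tangent,
                      feature, stage, role = "UNSPLIT", diagnostics = list()) {
  dimnames(coords) <- NULL
  dimnames(tangent) <- NULL
  new("StagedPointCloud", coords = coords, prevIdx = as.integer(prevIdx),
      nextIdx = as.integer(nextIdx), layerIndex = as.integer(layerIndex),
      pathId = as.integer(pathId), tangent = tangent, feature = feature,
      stage = stage, role = role, diagnostics = diagnostics)
}

# numeric value of G-code word <letter> per line, NA when absent
.gword <- function(lines, letter) {
  pat <- paste0(letter, "(-?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)")
  m <- regexpr(pat, lines, perl = TRUE)
  out <- rep(NA_real_, length(lines))
  hit <- m > 0
  out[hit] <- as.numeric(sub(pat, "\\1",
                             regmatches(lines, m), perl = TRUE))
  out
}

.metaFromComments <- function(comments, key) {
  pat <- paste0("(?i)", key, "\\s*[:=]\\s*(-?[0-9.]+)")
  hit <- grep(pat, comments, perl = TRUE, value = TRUE)
  if (!length(hit)) return(NA_real_)
  as.numeric(sub(paste0(".*", pat, ".*"), "\\1", hit[1], perl = TRUE))
}

#' Parse G-code into a toolpath model
#'
#' Reads a RepRap-style linear-move G-code file: \code{G0}/\code{G1} moves
#' with \code{X/Y/Z/E/F} words under \code{G90}/\code{G91} positioning and
#' \code{M82}/\code{M83}/\code{G92} extruder state. Extrusion segments are
#' moves with a positive extrusion delta; retractions and the subsequent
#' un-retract are travels, and extrusion resumes only once the cumulative
#' extrusion exceeds its pre-retraction maximum. Layer indices are assigned
#' by distinct ascending extrusion Z. Process metadata (layer height, line
#' width, extrusion multiplier) is taken from slicer header comments, then
#' from modal analysis of the Z steps, then from \code{defaults} (with a
#' warning).
#'
#' Arc moves (\code{G2}/\code{G3}) and inch mode (\code{G20}) are rejected.
#'
#' @param text character: either a file path or G-code source lines.
#' @param defaults list with fallback \code{layerHeight}, \code{lineWidth},
#'   \code{extrusionMultiplier}.
#' @return a \code{\linkS4class{GCodeToolpath}}
#' @export
parseGcode <- function(text,
                       defaults = list(layerHeight = 0.2, lineWidth = 0.4,
                                       extrusionMultiplier = 1)) {
  lines <- if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    readLines(text, warn = FALSE)
  else unlist(strsplit(text, "\n", fixed = TRUE))
  comments <- sub("^[^;]*;", "", lines[grepl(";", lines, fixed = TRUE)])
  code <- toupper(trimws(sub(";.*$", "", lines)))
  keep <- nzchar(code)
  lineNo <- which(keep)
  code <- code[keep]
  # feature tags (";TYPE:WALL-OUTER" style) apply to following moves
  featTag <- rep(NA_character_, length(lines))
  tl <- grepl("^\\s*;\\s*TYPE:", lines, ignore.case = TRUE)
  featTag[tl] <- toupper(trimws(sub("^\\s*;\\s*TYPE:", "", lines[tl],
                                    ignore.case = TRUE)))
  op <- sub("^([A-Z][0-9]+).*$", "\\1", code)
  op[!grepl("^[A-Z][0-9]+", code)] <- ""
  if (any(op %in% c("G2", "G3")))
    stop("unsupported G-code dialect: arc moves (G2/G3) are not supported")
  if (any(op == "G20"))
    stop("unit error: inch mode (G20) is not supported; units must be mm")
  X <- .gword(code, "X"); Y <- .gword(code, "Y"); Z <- .gword(code, "Z")
  E <- .gword(code, "E"); F_ <- .gword(code, "F")

  n <- length(code)
  sx1 <- sy1 <- sz1 <- sx2 <- sy2 <- sz2 <- sde <- numeric(n)
  spath <- integer(n)
  sfeat <- character(n)
  nseg <- 0L
  tx1 <- ty1 <- tz1 <- tx2 <- ty2 <- tz2 <- numeric(n)
  ntrav <- 0L

  px <- py <- pz <- NA_real_
  absMode <- TRUE
  eAbs <- TRUE
  eCmd <- 0
  cumE <- 0
  maxE <- 0
  pathId <- 0L
  lastWasSeg <- FALSE
  # carry the most recent ;TYPE: tag forward to each command line
  featCum <- rep(NA_character_, n)
  allTags <- featTag
  tagLines <- which(!is.na(allTags))
  if (length(tagLines)) {
    idx <- findInterval(lineNo, tagLines)
    featCum[idx > 0] <- allTags[tagLines[idx[idx > 0]]]
  }

  for (i in seq_len(n)) {
    o <- op[i]
    if (o == "G90") { absMode <- TRUE; eAbs <- TRUE; next }
    if (o == "G91") { absMode <- FALSE; eAbs <- FALSE; next }
    if (o == "M82") { eAbs <- TRUE; next }
    if (o == "M83") { eAbs <- FALSE; next }
    if (o == "G92") {
      if (!is.na(X[i])) px <- X[i]
      if (!is.na(Y[i])) py <- Y[i]
      if (!is.na(Z[i])) pz <- Z[i]
      if (!is.na(E[i])) eCmd <- E[i]  # rebase; cumulative extrusion unchanged
      next
    }
    if (o != "G0" && o != "G1") next
    nx <- if (!is.na(X[i])) { if (absMode || is.na(px)) X[i] else px + X[i] } else px
    ny <- if (!is.na(Y[i])) { if (absMode || is.na(py)) Y[i] else py + Y[i] } else py
    nz <- if (!is.na(Z[i])) { if (absMode || is.na(pz)) Z[i] else pz + Z[i] } else pz
    de <- 0
    if (!is.na(E[i])) {
      de <- if (eAbs) E[i] - eCmd else E[i]
      eCmd <- if (eAbs) E[i] else eCmd
      cumE <- cumE + de
    }
    moved <- (!is.na(px) && !is.na(nx) && nx != px) ||
             (!is.na(py) && !is.na(ny) && ny != py) ||
             (!is.na(pz) && !is.na(nz) && nz != pz) ||
             (is.na(px) || is.na(py) || is.na(pz))
    known <- !is.na(px) && !is.na(py) && !is.na(pz) &&
             !is.na(nx) && !is.na(ny) && !is.na(nz)
    extruding <- known && de > 0 && cumE > maxE + 1e-12
    if (extruding) {
      if (nz != pz)
        stop("malformed segment at line ", lineNo[i],
             ": non-planar extrusion move (z ", pz, " -> ", nz, ")")
      newPath <- !lastWasSeg ||
        (nseg > 0 && (sx2[nseg] != px || sy2[nseg] != py || sz2[nseg] != pz))
      if (newPath) pathId <- pathId + 1L
      nseg <- nseg + 1L
      sx1[nseg] <- px; sy1[nseg] <- py; sz1[nseg] <- pz
      sx2[nseg] <- nx; sy2[nseg] <- ny; sz2[nseg] <- nz
      sde[nseg] <- cumE - max(maxE, cumE - de)
      spath[nseg] <- pathId
      sfeat[nseg] <- featCum[i]
      lastWasSeg <- TRUE
    } else if (moved && known) {
      ntrav <- ntrav + 1L
      tx1[ntrav] <- px; ty1[ntrav] <- py; tz1[ntrav] <- pz
      tx2[ntrav] <- nx; ty2[ntrav] <- ny; tz2[ntrav] <- nz
      lastWasSeg <- FALSE
    } else if (!moved && de != 0) {
      # retract / un-retract without motion: path break
      lastWasSeg <- FALSE
    }
    maxE <- max(maxE, cumE)
    px <- nx; py <- ny; pz <- nz
  }

  segments <- data.frame(
    x1 = sx1[seq_len(nseg)], y1 = sy1[seq_len(nseg)], z1 = sz1[seq_len(nseg)],
    x2 = sx2[seq_len(nseg)], y2 = sy2[seq_len(nseg)], z2 = sz2[seq_len(nseg)],
    de = sde[seq_len(nseg)], pathId = spath[seq_len(nseg)],
    feature = sfeat[seq_len(nseg)], stringsAsFactors = FALSE)
  travels <- data.frame(
    x1 = tx1[seq_len(ntrav)], y1 = ty1[seq_len(ntrav)], z1 = tz1[seq_len(ntrav)],
    x2 = tx2[seq_len(ntrav)], y2 = ty2[seq_len(ntrav)], z2 = tz2[seq_len(ntrav)])
  zlv <- sort(unique(segments$z1))
  segments$layer <- if (nseg) match(segments$z1, zlv) - 1L else integer(0)
  segments <- segments[, c("x1","y1","z1","x2","y2","z2","de","layer",
                           "pathId","feature")]

  h <- .metaFromComments(comments, "layer[_ ]?height")
  w <- .metaFromComments(comments, "(?:line[_ ]?width|extrusion[_ ]?width|nozzle[_ ]?diameter)")
  em <- .metaFromComments(comments, "extrusion[_ ]?multiplier")
  metaSource <- "header"
  if (is.na(h)) {
    dz <- diff(zlv)
    if (length(dz)) {
      h <- as.numeric(names(sort(table(signif(dz, 6)), decreasing = TRUE))[1])
      metaSource <- "modal-z"
    } else {
      h <- defaults$layerHeight
      metaSource <- "defaults"
      warning("layer height not found in header; using default ", h, " mm")
    }
  }
  if (is.na(w)) {
    w <- defaults$lineWidth
    if (metaSource == "header") metaSource <- "header+defaults"
    warning("line width not found in header; using default ", w, " mm")
  }
  if (is.na(em)) em <- defaults$extrusionMultiplier

  new("GCodeToolpath", segments = segments, travels = travels,
      meta = list(layerHeight = h, lineWidth = w, extrusionMultiplier = em,
                  sourceDialect = "reprap-linear", metaSource = metaSource))
}

#' Sample the raw nozzle-centerline point cloud (PC1)
#'
#' Every extrusion segment contributes its two endpoints plus intermediate
#' samples spaced at most \code{spacing} apart, so that rasterization at a
#' voxel size of \code{2 * spacing} cannot skip voxels. Chain links follow
#' G-code order and break at travels; the per-point tangent is the central
#' difference between the neighbouring original G-code vertices (one-sided at
#' open path ends, wrapped on closed contours).
#'
#' @param tp a \code{GCodeToolpath}
#' @param spacing maximum sample spacing along the path (mm)
#' @return a \code{\linkS4class{StagedPointCloud}} at stage \code{PC1}
#' @export
extractCenterlinePoints <- function(tp, spacing = 0.05) {
  stopifnot(spacing > 0)
  S <- tp@segments
  if (!nrow(S)) stop("empty toolpath: no extrusion segments to sample")
  outC <- vector("list", length(unique(S$pathId)))
  outT <- vector("list", length(outC))
  outL <- vector("list", length(outC))
  outF <- vector("list", length(outC))
  outP <- vector("list", length(outC))
  k <- 0L
  for (pid in unique(S$pathId)) {
    P <- S[S$pathId == pid, , drop = FALSE]
    m <- nrow(P)
    # path vertices v0..vm
    vx <- c(P$x1[1], P$x2); vy <- c(P$y1[1], P$y2); vz <- c(P$z1[1], P$z2)
    closed <- sqrt((vx[1] - vx[m + 1])^2 + (vy[1] - vy[m + 1])^2 +
                   (vz[1] - vz[m + 1])^2) < 1e-6
    # tangent at each vertex: central difference between neighbouring vertices
    vtx <- vty <- numeric(m + 1)
    for (vi in seq_len(m + 1)) {
      ip <- vi - 1L; inx <- vi + 1L
      if (closed) {
        if (ip < 1) ip <- m          # vertex m == vertex 0
        if (inx > m + 1) inx <- 2L
      } else {
        if (ip < 1) ip <- vi
        if (inx > m + 1) inx <- vi
      }
      dx <- vx[inx] - vx[ip]; dy <- vy[inx] - vy[ip]
      L <- sqrt(dx * dx + dy * dy)
      if (L < 1e-12) { vtx[vi] <- NA_real_; vty[vi] <- NA_real_ }
      else { vtx[vi] <- dx / L; vty[vi] <- dy / L }
    }
    pts <- vector("list", m)
    tgs <- vector("list", m)
    for (si in seq_len(m)) {
      dx <- P$x2[si] - P$x1[si]; dy <- P$y2[si] - P$y1[si]
      len <- sqrt(dx * dx + dy * dy)
      if (len < 1e-12) {
        pts[[si]] <- cbind(P$x1[si], P$y1[si], P$z1[si])
        tgs[[si]] <- cbind(vtx[si], vty[si])
        next
      }
      nint <- max(1L, ceiling(len / spacing - 1e-9))
      tpar <- seq(0, 1, length.out = nint + 1)
      pm <- cbind(P$x1[si] + tpar * dx, P$y1[si] + tpar * dy,
                  rep(P$z1[si], nint + 1))
      # tangents: vertex tangents at the two ends, segment direction inside
      tg <- cbind(rep(dx / len, nint + 1), rep(dy / len, nint + 1))
      tg[1, ] <- c(vtx[si], vty[si])
      tg[nint + 1, ] <- c(vtx[si + 1], vty[si + 1])
      pts[[si]] <- pm
      tgs[[si]] <- tg
    }
    k <- k + 1L
    outC[[k]] <- do.call(rbind, pts)
    outT[[k]] <- do.call(rbind, tgs)
    npp <- vapply(pts, nrow, 1L)
    outL[[k]] <- rep(P$layer, npp)
    outF[[k]] <- rep(P$feature, npp)
    outP[[k]] <- rep(pid, sum(npp))
  }
  coords <- do.call(rbind, outC)
  tangent <- do.call(rbind, outT)
  layer <- unlist(outL)
  feat <- unlist(outF)
  path <- unlist(outP)
  np <- nrow(coords)
  prv <- c(NA_integer_, seq_len(np - 1))
  nxt <- c(seq_len(np)[-1], NA_integer_)
  brk <- which(diff(path) != 0)
  nxt[brk] <- NA_integer_
  prv[brk + 1L] <- NA_integer_
  .newCloud(coords, prv, nxt, layer, path, tangent, feat, stage = "PC1")
}
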