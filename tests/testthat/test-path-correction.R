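# A compact scene whose stages are shared across tests (built in the helper).

test_that("shell filtering keeps perimeters and drops interior infill", {
  st <- fixtureBoxStages()
  pc1 <- st$pc1; pc2 <- st$pc2
  expect_identical(stage(pc2), "PC2")
  # mid layers: outer-perimeter points survive, infill points do not
  midMask1 <- pc1@layerIndex == 5
  feat1 <- pc1@feature[midMask1]
  midMask2 <- pc2@layerIndex == 5
  feat2 <- pc2@feature[midMask2]
  expect_true(all(feat2 == "WALL-OUTER"))
  expect_true(any(feat1 == "FILL"))      # infill existed before filtering
  expect_false(any(feat2 == "FILL"))
  # retained fraction of the mid layer equals the outer-perimeter share
  expect_equal(sum(feat2 == "WALL-OUTER"),
               sum(feat1 == "WALL-OUTER"))

  # a thin single-wall line keeps all points (everything is shell)
  tp <- suppressWarnings(parseGcode(
    c("G90", "M82", "G1 X0 Y0 Z0.2 E0", "G1 X10 Y0 E0.5")))
  pcl <- extractCenterlinePoints(tp, 0.05)
  mapl <- classifyLabels(voxelize(pcl, list(lineWidth = 0.4,
                                            layerHeight = 0.2), 0.1))
  expect_equal(nPoints(shellFilter(pcl, mapl)), nPoints(pcl))
})

test_that("XY correction applies the -w/2 offset with the infill verdict", {
  st <- fixtureBoxStages()
  pc3 <- st$pc3
  expect_identical(stage(pc3), "PC3")
  # mid-layer outer-perimeter points land exactly on the model surface:
  # the model box spans [15, 35] x [0, 20]
  mid <- pc3@layerIndex == 5 & !is.na(pc3@pathId) &
    coords(pc3)[, 1] > 12     # model only (calibration object is x < 11)
  xy <- coords(pc3)[mid, 1:2, drop = FALSE]
  dWall <- pmin(abs(xy[, 1] - 15), abs(xy[, 1] - 35),
                abs(xy[, 2] - 0), abs(xy[, 2] - 20))
  # away from corners the offset is exact; corners use bisector tangents
  expect_gt(mean(dWall < 1e-6), 0.95)
  expect_lt(max(dWall), 0.2)

  # no PC3 point lies in an INTERIOR voxel (XY verification rule)
  expect_false(any(isInfill(coords(pc3), st$map)))

  # error-drop diagnostic exists and is small on a clean fixture
  expect_lt(st$pc4@diagnostics$xyErrorDrop / nPoints(st$pc2), 0.01)

  # stage machine forbids re-application
  expect_error(xyCorrect(pc3, st$map, 0.4), "PC2")
  expect_error(zCorrect(st$pc4, st$map, 0.2), "PC3")
})

test_that("a free-standing single line keeps both offset candidates", {
  tp <- suppressWarnings(parseGcode(
    c("G90", "M82", "G1 X0 Y0 Z0.2 E0", "G1 X10 Y0 E0.5")))
  pc1 <- extractCenterlinePoints(tp, 0.05)
  map <- classifyLabels(voxelize(pc1, list(lineWidth = 0.4,
                                           layerHeight = 0.2), 0.1))
  pc2 <- shellFilter(pc1, map)
  pc3 <- xyCorrect(pc2, map, 0.4)
  # both candidates at y = +/- 0.2 are retained
  expect_equal(nPoints(pc3), 2 * nPoints(pc2))
  ys <- sort(unique(round(coords(pc3)[, 2], 6)))
  expect_equal(ys, c(-0.2, 0.2))
  expect_equal(pc3@diagnostics$xySingleLine, nPoints(pc2))
})

test_that("outward offset is correct on a curved (n-gon) perimeter", {
  # filled 64-gon cylinder: outer-perimeter points must offset outward to
  # the polygon surface, radius ~ R
  R <- 8
  scene <- composeScene(ngonPrismMesh(R, 64, 1.2), clearance = 6)
  g <- miniSlice(scene)
  st <- suppressWarnings(runCompare(g, scene@modelRef, scene@coRef,
                                    stages = TRUE))
  ctrRef <- c(mean(range(scene@modelRef@vertices[, 1])),
              mean(range(scene@modelRef@vertices[, 2])))
  pc3 <- st$pc3
  mid <- pc3@layerIndex == 3 & !is.na(pc3@pathId) &
    pc3@feature == "WALL-OUTER" & coords(pc3)[, 1] > 12  # model only
  rad <- sqrt(rowSums(sweep(coords(pc3)[mid, 1:2, drop = FALSE],
                            2, ctrRef)^2))
  # mean radial distance approximates the apothem..R band of the n-gon
  apothem <- R * cos(pi / 64)
  expect_gt(mean(rad), apothem - 0.02)
  expect_lt(mean(rad), R + 0.02)
})

test_that("Z correction moves points to deposition planes", {
  st <- fixtureBoxStages()
  pc4 <- st$pc4
  expect_identical(stage(pc4), "PC4")
  h <- 0.2
  z <- coords(pc4)[, 3]
  planes <- seq(0, max(z) + h, by = h)
  dPlane <- vapply(z, function(zz) min(abs(zz - planes)), numeric(1))
  expect_gte(mean(dPlane <= 0.1) * 100, 99.9)

  # side-wall points moved down by h; top-layer points stay
  pc3 <- st$pc3
  sel1 <- pc3@layerIndex == 1 & pc3@feature == "WALL-OUTER"
  z1 <- coords(pc4)[sel1, 3]
  # corner bisector candidates sit just outside the solid and legitimately
  # classify as superior edge (stay on the upper plane); walls move down
  expect_true(all(abs(z1 - 0.2) < 1e-9 | abs(z1 - 0.4) < 1e-9))
  expect_gt(mean(abs(z1 - 0.2) < 1e-9), 0.95)
  # model top layer is layer 9 (2 mm / 0.2): superior edge stays at 2.0
  topSel <- pc3@layerIndex == 9 & pc3@feature == "WALL-OUTER" &
    coords(pc3)[, 1] > 12   # model only (calibration object is x < 11)
  expect_true(all(abs(coords(pc4)[topSel, 3] - 2.0) < 1e-9))
  expect_gt(pc4@diagnostics$zSuperiorEdge, 0)
})
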