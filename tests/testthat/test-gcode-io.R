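test_that("absolute and relative extrusion state machines parse correctly", {
  tp <- suppressWarnings(parseGcode(
    c("G90", "M82", "G1 X0 Y0 Z0.2 E0", "G1 X10 Y0 E0.5")))
  expect_equal(nrow(tp@segments), 1)
  expect_equal(unlist(tp@segments[1, c("x1", "y1", "z1", "x2", "y2", "z2")]),
               c(x1 = 0, y1 = 0, z1 = 0.2, x2 = 10, y2 = 0, z2 = 0.2))
  expect_equal(tp@segments$de, 0.5)
  expect_equal(tp@segments$layer, 0L)

  # relative E: retraction and the post-retraction travel extrude nothing
  tp2 <- suppressWarnings(parseGcode(
    c("M83", "G1 X0 Y0 Z0.2 E0.0", "G1 X10 E0.4", "G1 E-0.8", "G1 X20")))
  expect_equal(nrow(tp2@segments), 1)
  expect_equal(tp2@segments$x2, 10)

  # extrusion resumes only above the pre-retraction maximum (absolute E)
  tp3 <- suppressWarnings(parseGcode(
    c("G90", "M82", "G1 X0 Y0 Z0.2 E0", "G1 X10 E0.4", "G1 E-0.4",
      "G1 X20", "G1 E0.4", "G1 X30 E0.8")))
  expect_equal(nrow(tp3@segments), 2)
  expect_equal(tp3@segments$de, c(0.4, 0.4))

  # G92 rebases E without creating extrusion
  tp4 <- suppressWarnings(parseGcode(
    c("G90", "M82", "G1 X0 Y0 Z0.2 E0", "G1 X10 E0.4", "G92 E0",
      "G1 X20 E0.4")))
  expect_equal(tp4@segments$de, c(0.4, 0.4))
})

test_that("unsupported dialects are rejected", {
  expect_error(parseGcode("G2 X5 Y5 I2 J0 E0.3"), "arc")
  expect_error(parseGcode(c("G20", "G1 X1 E1")), "inch|unit")
  expect_error(suppressWarnings(parseGcode(
    c("G90", "M82", "G1 X0 Y0 Z0.2 E0", "G1 X5 Z0.4 E0.5"))), "non-planar")
})

test_that("cumulative extrusion matches a line-by-line oracle", {
  g <- fixtureBoxGcode()[1:100]
  tp <- parseGcode(paste(g, collapse = "\n"))
  expect_equal(sum(tp@segments$de), oracleExtrusionTotal(g), tolerance = 1e-9)

  # and on the full fixture file
  gAll <- fixtureBoxGcode()
  tpAll <- parseGcode(gAll)
  expect_equal(sum(tpAll@segments$de), oracleExtrusionTotal(gAll),
               tolerance = 1e-9)
})

test_that("parsing is deterministic and meta comes from the header", {
  g <- fixtureBoxGcode()
  tp1 <- parseGcode(g)
  tp2 <- parseGcode(g)
  expect_identical(tp1@segments, tp2@segments)
  expect_equal(tp1@meta$layerHeight, 0.2)
  expect_equal(tp1@meta$lineWidth, 0.4)
  expect_equal(tp1@meta$metaSource, "header")
  # layer indices are non-decreasing in file order
  expect_false(is.unsorted(tp1@segments$layer))
})

test_that("centerline sampling covers segments at the requested density", {
  tp <- suppressWarnings(parseGcode(
    c("G90", "M82", "G1 X0 Y0 Z0.2 E0", "G1 X10 Y0 E0.5")))
  pc <- extractCenterlinePoints(tp, 0.05)
  expect_equal(nPoints(pc), 201)
  expect_identical(stage(pc), "PC1")
  gaps <- sqrt(rowSums(diff(coords(pc))^2))
  expect_true(all(gaps <= 0.05 + 1e-12))
  # every sampled point lies exactly on its source segment (y = 0, z = 0.2)
  expect_true(all(abs(coords(pc)[, 2]) < 1e-12))
  expect_true(all(abs(coords(pc)[, 3] - 0.2) < 1e-12))

  # zero-length segment contributes a single point
  tpz <- suppressWarnings(parseGcode(
    c("G90", "M82", "G1 X0 Y0 Z0.2 E0", "G1 X0 Y0 E0.5")))
  expect_equal(nPoints(extractCenterlinePoints(tpz, 0.05)), 1)

  # travels break the chain links
  tpt <- suppressWarnings(parseGcode(
    c("G90", "M82", "G1 X0 Y0 Z0.2 E0", "G1 X1 E0.1",
      "G0 X5", "G1 X6 E0.2")))
  pct <- extractCenterlinePoints(tpt, 0.5)
  br <- which(is.na(pct@nextIdx))
  expect_true(length(br) >= 2)       # one mid-cloud break plus the end
  expect_true(any(br < nPoints(pct)))
})

test_that("chain links are mutual and point count >= 2x segment count", {
  g <- fixtureBoxGcode()
  tp <- parseGcode(g)
  pc <- extractCenterlinePoints(tp, 0.05)
  expect_gte(nPoints(pc), 2 * nrow(tp@segments))
  ok <- which(!is.na(pc@prevIdx))
  expect_true(all(pc@nextIdx[pc@prevIdx[ok]] == ok))
})

test_that("STL round trips preserve geometry", {
  cube <- fixtureUnitCube()
  expect_equal(nrow(meshFaces(cube)), 12)
  expect_equal(meshVolume(cube), 1.0)

  fa <- tempfile(fileext = ".stl")
  writeSTL(cube, fa, ascii = TRUE)
  ra <- readSTL(fa)
  expect_equal(nrow(meshFaces(ra)), 12)
  expect_equal(meshVolume(ra), 1.0, tolerance = 1e-9)

  # binary round trip of a larger mesh within float32 precision
  m <- ngonPrismMesh(7.3, 64, 4.2)
  fb <- tempfile(fileext = ".stl")
  writeSTL(m, fb)
  rb <- readSTL(fb)
  expect_equal(nrow(meshFaces(rb)), nrow(meshFaces(m)))
  expect_equal(meshVolume(rb), meshVolume(m), tolerance = 1e-4)

  # truncated binary STL errors out
  raw <- readBin(fb, "raw", file.info(fb)$size)
  ft <- tempfile(fileext = ".stl")
  writeBin(raw[1:200], ft)
  expect_error(readSTL(ft), "truncated|malformed")
})

test_that("point-cloud export writes XYZ and PLY", {
  pc <- fixtureBoxStages()$pc4
  fx <- tempfile(fileext = ".xyz")
  writePointCloud(pc, fx, "xyz")
  expect_equal(nrow(utils::read.table(fx)), nPoints(pc))
  fp <- tempfile(fileext = ".ply")
  writePointCloud(pc, fp, "ply")
  expect_match(readLines(fp, n = 1), "ply")
})
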