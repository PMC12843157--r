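# helper: build a PC4-tagged cloud from explicit chains (list of n x 3
# matrices); each chain becomes one linked path
chainCloud <- function(chains, layer = 0L) {
  coords <- do.call(rbind, chains)
  pid <- rep(seq_along(chains), vapply(chains, nrow, 1L))
  lk <- slicerQC:::.rethreadLinks(pid)
  slicerQC:::.newCloud(coords, lk$prv, lk$nxt,
                       rep(layer, nrow(coords)), pid,
                       matrix(NA_real_, nrow(coords), 2),
                       rep(NA_character_, nrow(coords)), "PC4")
}

sq <- function(a, z = 0.2, x0 = 0, y0 = 0) {
  rbind(c(x0, y0, z), c(x0 + a, y0, z), c(x0 + a, y0 + a, z),
        c(x0, y0 + a, z), c(x0, y0, z))
}

test_that("closed chains become polygons with even-odd nesting", {
  cs <- buildLayerContours(chainCloud(list(sq(10))), 0L, 0.2)
  expect_equal(length(cs@contours), 1)
  expect_equal(length(cs@openChains), 0)
  expect_equal(slicerQC:::.polyArea(cs@contours[[1]]), 100)  # CCW outer

  # square with inner square hole: outer CCW, hole CW
  cs2 <- buildLayerContours(chainCloud(list(sq(10), sq(4, x0 = 3, y0 = 3))),
                            0L, 0.2)
  areas <- sort(vapply(cs2@contours, slicerQC:::.polyArea, numeric(1)))
  expect_equal(areas, c(-16, 100))

  # a 0.5 mm endpoint gap exceeds the closure tolerance
  openChain <- sq(10)[1:4, ]
  openChain <- rbind(openChain, c(0, 9.5, 0.2))
  cs3 <- buildLayerContours(chainCloud(list(openChain)), 0L, 0.2, eps = 0.1)
  expect_equal(length(cs3@contours), 0)
  expect_equal(length(cs3@openChains), 1)
})

test_that("layer extrusion produces watertight slabs with area x h volume", {
  cs <- buildLayerContours(chainCloud(list(sq(10))), 0L, 0.2)
  slab <- extrudeLayer(cs)
  expect_true(isWatertight(slab))
  expect_equal(meshVolume(slab), 20.0, tolerance = 1e-9)

  # annulus: outer 10 x 10 with 4 x 4 hole
  cs2 <- buildLayerContours(chainCloud(list(sq(10), sq(4, x0 = 3, y0 = 3))),
                            0L, 0.2)
  slab2 <- extrudeLayer(cs2)
  expect_true(isWatertight(slab2))
  expect_equal(meshVolume(slab2), (100 - 16) * 0.2, tolerance = 1e-9)

  # L-shaped polygon against the shoelace oracle
  L <- rbind(c(0, 0, 0.2), c(8, 0, 0.2), c(8, 3, 0.2), c(3, 3, 0.2),
             c(3, 8, 0.2), c(0, 8, 0.2), c(0, 0, 0.2))
  csL <- buildLayerContours(chainCloud(list(L)), 0L, 0.2)
  slabL <- extrudeLayer(csL)
  expect_true(isWatertight(slabL))
  expect_equal(meshVolume(slabL),
               abs(oraclePolyArea(csL@contours[[1]])) * 0.2,
               tolerance = 1e-9)
})

test_that("slab merging cancels identical interfaces and keeps treads", {
  mk <- function(z0, x0 = 0) {
    cs <- buildLayerContours(chainCloud(list(sq(10, z = z0 + 0.2, x0 = x0)),
                                        layer = as.integer(z0 / 0.2)),
                             as.integer(z0 / 0.2), 0.2)
    extrudeLayer(cs)
  }
  s1 <- mk(0); s2 <- mk(0.2)
  merged <- mergeLayers(list(s1, s2))
  expect_true(isWatertight(merged))
  expect_equal(meshVolume(merged), 40, tolerance = 1e-9)
  # interface caps removed: fewer faces than the plain union
  expect_lt(nrow(meshFaces(merged)),
            nrow(meshFaces(s1)) + nrow(meshFaces(s2)))

  # staircase offset: tread faces retained, volume conserved
  s3 <- mk(0.2, x0 = 4)
  stair <- mergeLayers(list(s1, s3))
  expect_true(isWatertight(stair))
  expect_equal(meshVolume(stair), 40, tolerance = 1e-9)
  expect_equal(nrow(meshFaces(stair)),
               nrow(meshFaces(s1)) + nrow(meshFaces(s3)))

  # single slab passes through; overlapping slabs are rejected
  expect_identical(mergeLayers(list(s1)), s1)
  expect_error(mergeLayers(list(s1, mk(0.1))), "overlap")
})

test_that("volume conservation holds across merged fixture layers", {
  st <- fixtureBoxStages()
  recon <- reconstructMesh(st$pcm, 0.2, 0.1, map = st$map)
  expect_true(isWatertight(recon$mesh))
  expect_equal(meshVolume(recon$mesh), sum(recon$layers$volume),
               tolerance = 1e-9 * abs(meshVolume(recon$mesh)))
  # layer diagnostics cover all ten layers of the 2 mm box
  expect_equal(nrow(recon$layers), 10)
  expect_true(all(recon$layers$n_polygons >= 1))
})
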