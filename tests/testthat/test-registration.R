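test_that("calibration split finds the step object by its dimensions", {
  st <- fixtureBoxStages()
  sp <- splitCalibration(st$pc4, st$map, c(10, 6.25, 8.75))
  expect_identical(cloudRole(sp$pco), "CALIBRATION")
  expect_identical(cloudRole(sp$pcm), "MODEL")
  expect_equal(nPoints(sp$pco) + nPoints(sp$pcm), nPoints(st$pc4))
  bb <- unname(apply(coords(sp$pco), 2, function(v) diff(range(v))))
  expect_equal(bb[1], 10, tolerance = 0.05)
  expect_equal(bb[2], 6.25, tolerance = 0.05)
  expect_equal(bb[3], 8.75, tolerance = 0.05)  # partial top layer omitted
})

test_that("split errors on degenerate scenes", {
  # one component only
  tp <- parseGcode(miniSlice(composeScene(boxMesh(c(8, 8, 1)))))
  pc1 <- extractCenterlinePoints(tp, 0.05)
  # drop the calibration-object points to fake a single-component scene
  keep <- coords(pc1)[, 1] > 12
  lk <- slicerQC:::.rethreadLinks(pc1@pathId[keep])
  pcOne <- slicerQC:::.newCloud(coords(pc1)[keep, ], lk$prv, lk$nxt,
                                pc1@layerIndex[keep], pc1@pathId[keep],
                                pc1@tangent[keep, ], pc1@feature[keep],
                                "PC1")
  mapOne <- classifyLabels(voxelize(pcOne, tp@meta, 0.1))
  expect_error(splitCalibration(pcOne, mapOne, c(10, 6.25, 8.75)),
               "2 connected components")

  # two components, neither matching the calibration dimensions
  st <- fixtureBoxStages()
  expect_error(splitCalibration(st$pc4, st$map, c(30, 30, 30)),
               "calibration object not found")
})

test_that("center-of-mass pre-alignment recovers pure translations", {
  st <- fixtureBoxStages()
  sp <- splitCalibration(st$pc4, st$map, c(10, 6.25, 8.75))
  co <- fixtureBoxScene()@coRef
  t0 <- comPrealign(sp$pco, co)
  expect_equal(t0@rotation, diag(3))
  # identity placement: the prealignment is already small
  expect_lt(max(abs(t0@translation[1:2])), 0.3)

  shifted <- applyTransform(sp$pco, rigidTransform(diag(3), c(100, 100, 0)),
                            role = "CALIBRATION")
  t1 <- comPrealign(shifted, co)
  expect_equal(t1@translation[1:2] - t0@translation[1:2], c(-100, -100),
               tolerance = 0.05, ignore_attr = TRUE)

  zshift <- applyTransform(sp$pco, rigidTransform(diag(3), c(0, 0, 7.3)),
                           role = "CALIBRATION")
  t2 <- comPrealign(zshift, co)
  expect_equal(t2@translation[3] - t0@translation[3], -7.3, tolerance = 0.05)
})

test_that("ICP self-registration is the identity", {
  co <- makeCalibrationObject()
  # sample points exactly on the calibration surface (face grids)
  set.seed(3)
  V <- meshVertices(co); F <- meshFaces(co)
  pts <- do.call(rbind, lapply(seq_len(nrow(F)), function(f) {
    u <- matrix(stats::runif(60), ncol = 2)
    flip <- u[, 1] + u[, 2] > 1
    u[flip, ] <- 1 - u[flip, ]
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c_ <- V[F[f, 3], ]
    t(vapply(seq_len(nrow(u)), function(k)
      a + u[k, 1] * (b - a) + u[k, 2] * (c_ - a), numeric(3)))
  }))
  pc <- slicerQC:::.newCloud(pts, rep(NA_integer_, nrow(pts)),
                             rep(NA_integer_, nrow(pts)),
                             rep(0L, nrow(pts)), rep(1L, nrow(pts)),
                             matrix(NA_real_, nrow(pts), 2),
                             rep(NA_character_, nrow(pts)), "PC4",
                             "CALIBRATION")
  t <- icpRefine(pc, co, rigidTransform())
  expect_lt(max(abs(t@rotation - diag(3))), 1e-6)
  expect_lt(max(abs(t@translation)), 1e-6)
  expect_lt(attr(t, "icp")$rms, 1e-9)
})

test_that("ICP recovers a known rigid perturbation of the corrected cloud", {
  st <- fixtureBoxStages()
  sp <- splitCalibration(st$pc4, st$map, c(10, 6.25, 8.75))
  co <- fixtureBoxScene()@coRef
  t0 <- icpRefine(sp$pco, co, comPrealign(sp$pco, co))
  known <- rotationZ(3, c(50, 25, 0))
  moved <- applyTransform(sp$pco, known, role = "CALIBRATION")
  t1 <- icpRefine(moved, co, comPrealign(moved, co))
  # t1 must equal t0 composed with the inverse perturbation
  rel <- composeTransforms(invertTransform(t0),
                           composeTransforms(t1, known))
  expect_lt(max(abs(rel@translation)), 0.01)
  expect_lt(rotationAngle(rel), 0.05)
})

test_that("rigid transforms preserve structure and compose correctly", {
  st <- fixtureBoxStages()
  pcm <- st$pcm
  t <- rotationZ(4.2, c(12.5, -3.1, 0.7))
  moved <- applyTransform(pcm, t)
  expect_identical(cloudRole(moved), "TPCM")
  # identity is bit-identical
  idm <- applyTransform(pcm, rigidTransform(), role = pcm@role)
  expect_identical(coords(idm), coords(pcm))
  # t then t^-1 returns the original within 1e-9
  back <- applyTransform(moved, invertTransform(t), role = pcm@role)
  expect_lt(max(abs(coords(back) - coords(pcm))), 1e-9)
  # rigidity: pairwise distances preserved
  set.seed(1)
  idx <- sample(nPoints(pcm), 200)
  d0 <- dist(coords(pcm)[idx, ])
  d1 <- dist(coords(moved)[idx, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
})

test_that("transform serializes as a homogeneous matrix", {
  t <- rotationZ(10, c(1, 2, 3))
  js <- transformToJSON(t)
  m <- matrix(jsonlite::fromJSON(js)$matrix_row_major, 4, 4, byrow = TRUE)
  expect_equal(m[1:3, 1:3], t@rotation, ignore_attr = TRUE)
  expect_equal(m[1:3, 4], t@translation, ignore_attr = TRUE)
  expect_equal(m[4, ], c(0, 0, 0, 1))
})
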