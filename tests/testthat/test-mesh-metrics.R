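test_that("signed distances have face-normal magnitudes and signs", {
  cube <- fixtureUnitCube()
  expect_equal(signedPointMeshDistance(c(0.5, 0.5, 1.1), cube), 0.1,
               tolerance = 1e-12)
  expect_equal(signedPointMeshDistance(c(0.5, 0.5, 0.5), cube), -0.5,
               tolerance = 1e-12)
  expect_equal(signedPointMeshDistance(c(0.5, 0.5, 1.0), cube), 0,
               tolerance = 1e-12)
  # outside near an edge and a corner: positive, Euclidean magnitude
  expect_equal(signedPointMeshDistance(c(1.1, 1.1, 0.5), cube),
               sqrt(2) * 0.1, tolerance = 1e-12)
  expect_equal(signedPointMeshDistance(c(1.1, 1.1, 1.1), cube),
               sqrt(3) * 0.1, tolerance = 1e-12)
})

test_that("grid and brute-force routes agree exactly; R oracle confirms", {
  set.seed(7)
  mesh <- ngonPrismMesh(5, 24, 3)
  pts <- cbind(stats::runif(1000, -7, 7), stats::runif(1000, -7, 7),
               stats::runif(1000, -2, 5))
  g <- signedPointMeshDistance(pts, mesh, method = "grid", details = TRUE)
  b <- signedPointMeshDistance(pts, mesh, method = "brute", details = TRUE)
  expect_identical(g$distance, b$distance)
  expect_identical(g$triangle, b$triangle)

  # independent R oracle on a subsample (including a 2-triangle patch case)
  sub <- pts[seq(1, 1000, by = 40), ]
  expect_equal(signedPointMeshDistance(sub, mesh), oracleSignedDistance(sub, mesh),
               tolerance = 1e-9)
  patch <- TriangleMesh(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0)),
                        rbind(c(1, 2, 3), c(2, 4, 3)))
  q <- cbind(stats::runif(100, -1, 3), stats::runif(100, -1, 3),
             stats::runif(100, -1, 1))
  expect_equal(abs(signedPointMeshDistance(q, patch, method = "brute")),
               abs(oracleSignedDistance(q, patch)), tolerance = 1e-9)
})

test_that("surface metrics reproduce closed-form values and inequalities", {
  cube <- fixtureUnitCube()
  # cloud exactly on the surface
  on <- rbind(c(0.5, 0.5, 1), c(0.5, 0.5, 0), c(1, 0.25, 0.75))
  r0 <- surfaceMetrics(on, cube)
  expect_equal(r0@msd, 0); expect_equal(r0@rms, 0)
  expect_equal(r0@dMin, 0); expect_equal(r0@dMax, 0)

  # three points at signed distances {+0.1, -0.1, +0.2}
  p <- rbind(c(0.5, 0.5, 1.1), c(0.5, 0.5, 0.9), c(0.5, 0.5, 1.2))
  r <- surfaceMetrics(p, cube)
  expect_equal(r@msd, 0.2 / 3, tolerance = 1e-9)
  expect_equal(r@rms, sqrt(0.06 / 3), tolerance = 1e-9)
  expect_equal(r@dMin, -0.1)
  expect_equal(r@dMax, 0.2)

  # rms >= mean|d| >= |msd| on random inputs
  set.seed(11)
  q <- matrix(stats::runif(900, -0.5, 1.5), ncol = 3)
  d <- signedPointMeshDistance(q, cube)
  expect_gte(sqrt(mean(d^2)) + 1e-12, mean(abs(d)))
  expect_gte(mean(abs(d)) + 1e-12, abs(mean(d)))
})

test_that("metrics are invariant under a common rigid transform", {
  set.seed(5)
  mesh <- lBeamMesh(10, 4, 3)
  pts <- matrix(stats::runif(300, -1, 11), ncol = 3)
  r1 <- surfaceMetrics(pts, mesh)
  t <- rotationZ(33, c(5, -2, 1))
  ptsT <- sweep(pts %*% t(t@rotation), 2, t@translation, "+")
  r2 <- surfaceMetrics(ptsT, transformMesh(mesh, t))
  expect_equal(r1@msd, r2@msd, tolerance = 1e-9)
  expect_equal(r1@rms, r2@rms, tolerance = 1e-9)
  expect_equal(r1@dMin, r2@dMin, tolerance = 1e-9)
  expect_equal(r1@dMax, r2@dMax, tolerance = 1e-9)
})

test_that("volumes and volume differences follow the divergence theorem", {
  a <- boxMesh(c(10, 10, 10))
  b <- boxMesh(c(10, 10, 9.9))
  r <- volumeDifference(b, a)
  expect_equal(r@volumeDiff, -10, tolerance = 1e-9)
  expect_equal(r@volumeDiffRel, -1.0, tolerance = 1e-9)
  r0 <- volumeDifference(a, a)
  expect_equal(r0@volumeDiff, 0)
  expect_equal(r0@volumeDiffRel, 0)

  # inside-out cube is auto-reoriented
  flip <- TriangleMesh(meshVertices(a), meshFaces(a)[, c(1, 3, 2)])
  expect_equal(meshVolume(flip), -1000)
  expect_equal(volumeDifference(flip, a)@volumeRecon, 1000)

  # non-watertight input is refused with a boundary-edge count
  open <- TriangleMesh(meshVertices(a), meshFaces(a)[-1, ])
  expect_false(isWatertight(open))
  expect_gt(isWatertight(open, countBoundary = TRUE), 0)
  expect_error(volumeDifference(open, a), "not watertight")

  # volume additivity of a disjoint union
  two <- slicerQC:::.concatMeshes(list(boxMesh(c(2, 3, 4)),
                                       boxMesh(c(1, 1, 1), c(10, 0, 0))))
  expect_equal(meshVolume(two), 2 * 3 * 4 + 1, tolerance = 1e-9)
})
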