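test_that("isosurface of a single voxel is a closed unit-scale mesh", {
  a <- array(0L, c(3, 3, 3)); a[2, 2, 2] <- 1L
  m <- labelIsosurface(a, labels = 1L)
  expect_true(braincanvas:::.isClosed(m))
  v <- meshVolume(m)
  expect_gt(v, 0.4)
  expect_lt(v, 1.1)
})

test_that("isosurface volume converges to the analytic ball volume", {
  errs <- vapply(c(4L, 8L, 16L), function(r) {
    m <- labelIsosurface(digitalBall(r), labels = 1L)
    expect_true(braincanvas:::.isClosed(m))
    abs(meshVolume(m) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
  }, numeric(1))
  expect_lt(errs[2], 0.15)
  expect_true(all(diff(errs) < 0))  # error shrinks as the ball grows
})

test_that("isosurface rejects empty selections", {
  a <- array(1, c(4, 4, 4))
  expect_error(labelIsosurface(a, threshold = 2), "empty region")
  expect_error(labelIsosurface(a, labels = 99), "empty region")
  expect_error(labelIsosurface(a), "exactly one")
})

test_that("isosurface scales vertices by the voxel resolution", {
  a <- array(1L, c(4, 4, 4))
  m <- labelIsosurface(a, labels = 1L, resolution = 25)
  bb <- apply(vertices(m), 2, range)
  expect_equal(bb[1, ], c(0, 0, 0), tolerance = 1e-9)
  expect_equal(bb[2, ], c(100, 100, 100), tolerance = 1e-9)
  expect_equal(meshVolume(m) / 100^3, 1, tolerance = 0.05)
})

test_that("plane slicing keeps the stated half and caps the cut", {
  cube <- labelIsosurface(array(1L, c(4, 4, 4)), labels = 1L,
                          resolution = 25)
  v0 <- meshVolume(cube)
  half <- sliceMesh(cube, plane(c(50, 50, 50), c(1, 0, 0)), "below")
  expect_equal(meshVolume(half) / v0, 0.5, tolerance = 0.01)
  expect_true(all(vertices(half)[, 1] <= 50 + 1e-9))
  ## plane beyond the mesh: unchanged / empty
  same <- sliceMesh(cube, plane(c(1e4, 0, 0), c(1, 0, 0)), "below")
  expect_equal(meshVolume(same), v0)
  gone <- sliceMesh(cube, plane(c(-1e4, 0, 0), c(1, 0, 0)), "below")
  expect_true(isEmptyMesh(gone))
})

test_that("slicing conserves volume over random planes", {
  set.seed(31)
  ball <- labelIsosurface(digitalBall(6L), labels = 1L)
  cube <- labelIsosurface(array(1L, c(5, 5, 5)), labels = 1L)
  meshes <- list(ball, cube)
  for (i in 1:50) {
    m <- meshes[[(i %% 2L) + 1L]]
    cen <- colMeans(vertices(m))
    pl <- plane(cen + rnorm(3, 0, 2), rnorm(3))
    v <- meshVolume(m)
    vb <- meshVolume(sliceMesh(m, pl, "below"))
    va <- meshVolume(sliceMesh(m, pl, "above"))
    expect_lt(abs(vb + va - v) / v, 0.01)
  }
})

test_that("sphere glyph instancing multiplies the template", {
  set.seed(41)
  pts <- matrix(runif(30, 0, 100), 10, 3)
  m <- pointsToSpheres(pts, radius = 3, subdivisions = 1L)
  expect_equal(nrow(vertices(m)), 10L * 42L)
  expect_equal(nrow(faces(m)), 10L * 80L)
  one <- pointsToSpheres(matrix(0, 1, 3), radius = 7)
  bb <- apply(vertices(one), 2, range)
  expect_equal(bb[2, ] - bb[1, ], rep(14, 3), tolerance = 0.05 * 14)
  ## centroid of many glyphs equals the mean coordinate
  many <- matrix(runif(3000, 0, 1000), 1000, 3)
  g <- pointsToSpheres(many, radius = 2, subdivisions = 0L)
  expect_true(all(abs(colMeans(vertices(g)) - colMeans(many)) < 2))
  expect_true(isEmptyMesh(pointsToSpheres(matrix(0, 0, 3), radius = 1)))
  expect_error(pointsToSpheres(pts, radius = 0), "positive")
})

test_that("neuron meshes group SWC parts and track segment lengths", {
  p <- toySWC(tempfile(fileext = ".swc"))
  parts <- neuronToMeshes(readSWC(p))
  expect_setequal(names(parts), c("soma", "dendrites"))
  expect_equal(nrow(vertices(parts$soma)), 42L)  # one icosphere
  ## 2 capped tube segments: 2 x (2 rings x 8 + 2 centers)
  expect_equal(nrow(vertices(parts$dendrites)), 2L * 18L)

  swc <- tempfile(fileext = ".swc")
  makeSyntheticNeuron(swc, seed = 13, nBranchPoints = 3L)
  m <- readSWC(swc)
  parts <- neuronToMeshes(m, sides = 12L)
  nd <- m@nodes
  seg <- which(nd$parent_id != -1L & nd$type != 1L)
  pidx <- match(nd$parent_id[seg], nd$sample_id)
  lens <- sqrt(rowSums((as.matrix(nd[seg, c("x", "y", "z")]) -
                        as.matrix(nd[pidx, c("x", "y", "z")]))^2))
  ## each straight tube is a prism: volume = polygon area x length
  area <- 6 * sin(pi / 6) * 1.2^2  # 12-sided polygon, radius 1.2
  measured <- meshVolume(parts$dendrites) / area
  expect_equal(measured, sum(lens), tolerance = 0.01)
})

test_that("streamline tubes approximate cylinders and count components", {
  s <- new("Streamlines",
           paths = list(rbind(c(0, 0, 0), c(0, 0, 200))))
  m <- streamlinesToMesh(s, radius = 5)
  expect_equal(surfaceArea(m), 2 * pi * 5 * 200, tolerance = 0.1)
  at <- miniAtlas()
  p <- tempfile(fileext = ".json")
  makeSyntheticStreamlines(at, "MOs", 4L, p, seed = 8)
  tube <- streamlinesToMesh(readStreamlines(p), radius = 4)
  expect_equal(braincanvas:::.meshComponents(tube), 4L)
  expect_true(isEmptyMesh(streamlinesToMesh(new("Streamlines"), radius = 1)))
})

test_that("centers of mass and distances are exact on symmetric solids", {
  cube <- labelIsosurface(array(1L, c(4, 4, 4)), labels = 1L,
                          resolution = 25)
  expect_equal(centerOfMass(cube), c(50, 50, 50), tolerance = 1e-6)
  s1 <- icosphere(1L)
  s2 <- triMesh(s1@vertices +
                  matrix(c(10, 0, 0), nrow(s1@vertices), 3, byrow = TRUE),
                s1@faces)
  expect_equal(distanceBetween(s1, s2), 10, tolerance = 1e-6)
  expect_equal(distanceBetween(s1, s1), 0)
  expect_error(centerOfMass(emptyMesh()), "empty mesh")
})

test_that("containment matches the voxel-mask oracle", {
  ball <- digitalBall(8L)
  m <- labelIsosurface(ball, labels = 1L)
  cube <- labelIsosurface(array(1L, c(4, 4, 4)), labels = 1L)
  expect_true(pointInMesh(c(1.5, 1.5, 1.5), cube))
  expect_false(pointInMesh(c(50, 0, 0), cube))
  set.seed(51)
  n <- dim(ball)[1]
  pts <- matrix(runif(1500, 0, n), 500, 3)
  got <- pointInMesh(pts, m)
  vi <- pmin(floor(pts) + 1L, n)
  want <- ball[vi] == 1L
  expect_gte(mean(got == want), 0.98)
})

test_that("open meshes trigger a best-effort containment warning", {
  open <- triMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2, 3)))
  expect_warning(pointInMesh(c(0.1, 0.1, 0.1), open), "not closed")
})

test_that("mesh intersection distinguishes touching from distant solids", {
  s1 <- icosphere(2L)
  shift <- function(dx) triMesh(
    s1@vertices + matrix(c(dx, 0, 0), nrow(s1@vertices), 3, byrow = TRUE),
    s1@faces)
  expect_false(meshesIntersect(s1, shift(10)))
  expect_true(meshesIntersect(s1, shift(1)))
  expect_true(meshesIntersect(s1, shift(0.1)))  # near-coincident
  expect_false(meshesIntersect(s1, emptyMesh()))
})

test_that("geometry operations are deterministic", {
  ball <- digitalBall(5L)
  m1 <- labelIsosurface(ball, labels = 1L)
  m2 <- labelIsosurface(ball, labels = 1L)
  expect_identical(vertices(m1), vertices(m2))
  expect_identical(faces(m1), faces(m2))
  t1 <- tubeMesh(rbind(c(0, 0, 0), c(10, 10, 10)), 2)
  t2 <- tubeMesh(rbind(c(0, 0, 0), c(10, 10, 10)), 2)
  expect_identical(vertices(t1), vertices(t2))
})

test_that("smoothing relaxes the staircase while staying near the volume", {
  m0 <- labelIsosurface(digitalBall(6L), labels = 1L)
  m1 <- labelIsosurface(digitalBall(6L), labels = 1L, smoothing = 3L)
  expect_lt(surfaceArea(m1), surfaceArea(m0))  # smoother surface
  expect_gt(meshVolume(m1), 0.7 * meshVolume(m0))
})
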