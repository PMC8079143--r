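test_that("makeActor dispatches payloads to the right geometry", {
  set.seed(61)
  pts <- brainPoints(matrix(runif(30, 0, 100), 10, 3))
  a <- makeActor(pts, name = "cells", radius = 2)
  expect_s4_class(a, "SceneActor")
  expect_equal(a@kind, "points")
  expect_equal(nrow(vertices(a)), 10L * 42L)
  expect_equal(a@style@color, normalizeColor("salmon"))

  morph <- readSWC(toySWC(tempfile(fileext = ".swc")))
  acts <- makeActor(morph, name = "n1")
  expect_length(acts, 2L)
  expect_setequal(vapply(acts, function(x) x@name, character(1)),
                  c("n1_soma", "n1_dendrites"))
  expect_true(all(vapply(acts, function(x) x@kind == "neuron_part",
                         logical(1))))

  vals <- array(0, c(10, 10, 10)); vals[4:6, 4:6, 4:6] <- 10
  vg <- volumeGrid(vals, 2)
  va <- makeActor(vg, name = "expr", threshold = 5)
  direct <- labelIsosurface(vg, threshold = 5)
  expect_identical(vertices(va), vertices(direct))
  expect_error(makeActor(vg, name = "expr"), "threshold")
  expect_error(makeActor(pts, kind = "streamlines"), "cannot be wrapped")
})

test_that("makeActor leaves its payload untouched", {
  pts <- brainPoints(matrix(1:30, 10, 3))
  before <- pts@coordinates
  invisible(makeActor(pts, radius = 1))
  expect_identical(pts@coordinates, before)
})

test_that("actor meshes satisfy mesh invariants", {
  set.seed(62)
  pts <- brainPoints(matrix(runif(15, 0, 50), 5, 3))
  a <- makeActor(pts, radius = 1)
  expect_true(validObject(a@mesh))
  f <- faces(a)
  expect_true(all(f >= 1L & f <= nrow(vertices(a))))
  expect_false(any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
})

test_that("setStyle changes only the supplied fields", {
  a <- makeActor(icosphere(0L), name = "ball")
  a2 <- setStyle(a, alpha = 0.5)
  expect_equal(a2@style@alpha, 0.5)
  expect_equal(a2@style@color, a@style@color)
  a3 <- setStyle(a2, color = "#FF0000")
  expect_equal(a3@style@color, "#ff0000")
  expect_equal(a3@style@alpha, 0.5)
  expect_error(setStyle(a, alpha = 1.5), "alpha")
  expect_error(setStyle(a, color = "salmonz"), "did you mean")
})

test_that("color normalization accepts names, hex and RGB triples", {
  expect_equal(normalizeColor("salmon"), "#fa8072")
  expect_equal(normalizeColor("#AbCdEf"), "#abcdef")
  expect_equal(normalizeColor(c(255, 0, 0)), "#ff0000")
  expect_error(normalizeColor(c(300, 0, 0)), "0..255")
})
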