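test_that("scene creation adds the root actor and frames it", {
  at <- smallAtlas()
  sc <- brainScene(at)
  expect_length(actors(sc), 1L)
  expect_equal(actors(sc)[[1]]@name, "root")
  sc0 <- brainScene(at, addRoot = FALSE)
  expect_length(actors(sc0), 0L)
  ## default camera aims at the root bounding-box center
  bb <- apply(vertices(regionMesh(at, "root")), 2, range)
  expect_true(all(abs(sc@camera@focalPoint - colMeans(bb)) <=
                    resolutionUm(at)))
})

test_that("region actors use atlas colors and add atomically", {
  at <- smallAtlas()
  sc <- brainScene(at)
  sc2 <- addBrainRegion(sc, c("VISp", "MOs"), alpha = 0.5)
  expect_length(actors(sc2), 3L)
  visp <- structures(at)[structures(at)$acronym == "VISp", ]
  expect_equal(actors(sc2)[[2]]@style@color,
               normalizeColor(c(visp$r, visp$g, visp$b)))
  expect_equal(actors(sc2)[[2]]@style@alpha, 0.5)
  ## unknown acronym: error, scene unchanged
  expect_error(sc3 <- addBrainRegion(sc, c("VISp", "BAD")),
               "nearest matches")
  expect_length(actors(sc), 1L)
})

test_that("actor names are unique within a scene", {
  at <- smallAtlas()
  sc <- brainScene(at)
  a <- makeActor(icosphere(0L), name = "thing")
  sc <- addActor(sc, a)
  sc <- addActor(sc, a)
  nms <- vapply(actors(sc), function(x) x@name, character(1))
  expect_equal(anyDuplicated(nms), 0L)
  expect_true("thing_2" %in% nms)
})

test_that("scene slicing targets only the requested actors", {
  at <- smallAtlas()
  set.seed(71)
  cells <- makeSyntheticCells(at, "root", 200L, seed = 3)
  sc <- brainScene(at)
  sc <- addActor(sc, makeActor(cells, name = "cells", radius = 10,
                               subdivisions = 0L))
  mid <- colMeans(apply(vertices(regionMesh(at, "root")), 2, range))
  v0 <- meshVolume(actors(sc)[[1]])
  nv0 <- nrow(vertices(actors(sc)[[2]]))
  sliced <- sceneSlice(sc, plane(mid, c(0, 0, 1)), actorNames = "root")
  ## mirror-symmetric root halves within 2%
  expect_equal(meshVolume(actors(sliced)[[1]]) / v0, 0.5,
               tolerance = 0.02)
  ## untargeted points actor untouched
  expect_equal(nrow(vertices(actors(sliced)[[2]])), nv0)
})

test_that("slicing a cell cloud keeps about half the spheres", {
  at <- miniAtlas()
  cells <- makeSyntheticCells(at, "root", 2000L, seed = 5)
  glyphs <- makeActor(cells, name = "cells", radius = 3,
                      subdivisions = 0L)
  sc <- brainScene(at, addRoot = FALSE)
  sc <- addActor(sc, glyphs)
  mid <- colMeans(apply(cells@coordinates, 2, range))
  pl <- plane(mid, c(0, 0, 1))
  sliced <- sceneSlice(sc, pl)
  keptVerts <- nrow(vertices(actors(sliced)[[1]]))
  fracKept <- keptVerts / nrow(vertices(glyphs))
  ## per-center oracle: spheres whose center is below the plane survive
  below <- (cells@coordinates[, 3] - mid[3]) <= 0
  expect_equal(fracKept, mean(below), tolerance = 0.05)
  expect_equal(mean(below), 0.5, tolerance = 4 * sqrt(0.25 / 2000))
})

test_that("screenshots have exact dimensions and repeatable pixels", {
  at <- smallAtlas()
  sc <- brainScene(at)
  sc <- addActor(sc, setStyle(makeActor(icosphere(1L), name = "dot"),
                              color = "red"))
  p1 <- tempfile(fileext = ".png")
  p2 <- tempfile(fileext = ".png")
  renderScreenshot(sc, p1, width = 211, height = 137)
  renderScreenshot(sc, p2, width = 211, height = 137)
  img <- png::readPNG(p1)
  expect_equal(dim(img)[1:2], c(137L, 211L))
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  ## a visible actor leaves non-background pixels
  expect_gt(sum(img[, , 1] != 1 | img[, , 2] != 1 | img[, , 3] != 1), 0)
})

test_that("HTML export embeds one geometry per visible actor", {
  at <- smallAtlas()
  sc <- brainScene(at)
  sc <- addBrainRegion(sc, "TH")
  sc <- addActor(sc, setStyle(makeActor(icosphere(0L), name = "hidden"),
                              visible = FALSE))
  p <- tempfile(fileext = ".html")
  exportHTML(sc, p)
  txt <- paste(readLines(p), collapse = "\n")
  json <- sub('.*<script type="application/json" id="scene-data">\n', "",
              txt)
  json <- sub("\n</script>.*", "", json)
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_length(doc$geometries, 2L)  # root + TH; hidden excluded
  nms <- vapply(doc$geometries, function(g) g$name, character(1))
  expect_false("hidden" %in% nms)
  ## empty scene still yields a valid document
  p0 <- tempfile(fileext = ".html")
  exportHTML(brainScene(at, addRoot = FALSE), p0)
  txt0 <- paste(readLines(p0), collapse = "\n")
  json0 <- sub('.*<script type="application/json" id="scene-data">\n', "",
               txt0)
  json0 <- sub("\n</script>.*", "", json0)
  expect_length(jsonlite::fromJSON(json0,
                                   simplifyVector = FALSE)$geometries, 0L)
})

test_that("camera presets are derived from the root bounding box", {
  at <- smallAtlas()
  sc <- brainScene(at)
  for (nm in c("frontal", "sagittal", "top")) {
    cam <- cameraPreset(sc, nm)
    expect_s4_class(cam, "CameraPose")
    expect_false(all(cam@position == cam@focalPoint))
  }
  expect_error(cameraPreset(sc, "oblique"), "unknown camera preset")
})
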