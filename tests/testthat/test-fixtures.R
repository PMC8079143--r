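test_that("the generated bundle satisfies every atlas invariant", {
  at <- miniAtlas()
  expect_true(validObject(at))
  ann <- annotation(at)
  st <- structures(at)
  ## annotation labels only leaves
  labeled <- setdiff(unique(as.vector(ann)), 0L)
  leaves <- st$id[!st$id %in% st$parent_id]
  expect_true(all(labeled %in% leaves))
  expect_setequal(labeled, c(3L, 4L, 5L))
})

test_that("the annotation is exactly mirror-symmetric about the midline", {
  ann <- annotation(miniAtlas())
  g <- dim(ann)
  expect_identical(ann, ann[, , g[3]:1])
})

test_that("atlas generation is deterministic", {
  spec <- fixtureSpec(gridShape = c(16L, 12L, 14L), resolution = 50)
  d1 <- tempfile("det1"); d2 <- tempfile("det2")
  makeMiniAtlas(d1, spec)
  makeMiniAtlas(d2, spec)
  for (f in c("annotation.tiff", "structures.json", "metadata.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), info = f)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("fixture spec validates its parameters", {
  expect_error(fixtureSpec(gridShape = c(4L, 12L, 14L)), ">= 8")
  expect_error(fixtureSpec(resolution = 0), "positive")
  expect_error(makeMiniAtlas(tempfile(),
                             fixtureSpec(gridShape = c(8L, 8L, 8L),
                                         nRegions = 6L)),
               "generation error")
})

test_that("synthetic cells land inside their source region", {
  at <- miniAtlas()
  cells <- makeSyntheticCells(at, "VISp", 1000L, seed = 2)
  expect_equal(nRecords(cells), 1000L)
  expect_true(all(pointInRegion(at, cells@coordinates, "VISp")))
  expect_true(all(pointInRegion(at, cells@coordinates, "CTX",
                                includeSubstructures = TRUE)))
  expect_false(any(pointInRegion(at, cells@coordinates, "TH",
                                 includeSubstructures = TRUE)))
  expect_equal(nRecords(makeSyntheticCells(at, "VISp", 0L)), 0L)
  c1 <- makeSyntheticCells(at, "MOs", 50L, seed = 9)
  c2 <- makeSyntheticCells(at, "MOs", 50L, seed = 9)
  expect_identical(c1@coordinates, c2@coordinates)
  expect_error(makeSyntheticCells(at, "CTX", 1L, seed = 1), NA)
})

test_that("synthetic neurons parse and carry the requested branch count", {
  for (seed in 1:25) {
    nb <- (seed - 1L) %% 5L
    p <- tempfile(fileext = ".swc")
    makeSyntheticNeuron(p, seed = seed, nBranchPoints = nb)
    m <- readSWC(p)
    expect_equal(branchPoints(m), nb, info = sprintf("seed %d", seed))
    expect_true(all(m@nodes$radius > 0))
  }
  ## unbranched neurite: no node beyond the soma has 2 children
  p <- tempfile(fileext = ".swc")
  makeSyntheticNeuron(p, seed = 99, nBranchPoints = 0L)
  m <- readSWC(p)
  kids <- table(m@nodes$parent_id[m@nodes$parent_id != -1L])
  expect_true(all(kids == 1L))
})

test_that("streamlines start inside the source region", {
  at <- miniAtlas()
  p <- tempfile(fileext = ".json")
  makeSyntheticStreamlines(at, "TH", 3L, p, seed = 6)
  s <- readStreamlines(p)
  expect_equal(nRecords(s), 3L)
  starts <- t(vapply(s@paths, function(pp) pp[1, ], numeric(3)))
  expect_true(all(pointInRegion(at, starts, "TH")))
})

test_that("expression volumes are recovered by midpoint thresholding", {
  at <- miniAtlas()
  p <- tempfile(fileext = ".tiff")
  makeExpressionVolume(at, "VISp", p, seed = 12)
  vol <- readVolumeTIFF(p)
  expect_equal(dim(vol@values), dim(annotation(at)))
  hot <- annotation(at) == 4L
  recovered <- vol@values >= (100 + 10) / 2
  expect_gte(sum(recovered & hot) / sum(hot), 0.90)
  ## few false positives outside the hot region
  expect_lt(sum(recovered & !hot) / sum(!hot), 0.01)
})
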