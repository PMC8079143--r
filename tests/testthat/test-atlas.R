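test_that("atlas bundle loads with the expected structure tree", {
  at <- miniAtlas()
  st <- structures(at)
  expect_equal(nrow(st), 5L)
  expect_setequal(st$acronym, c("root", "CTX", "TH", "VISp", "MOs"))
  expect_equal(sum(is.na(st$parent_id)), 1L)
  expect_true(all(st$r >= 0 & st$r <= 255))
})

test_that("loading is deterministic and validates its inputs", {
  d <- miniAtlasDir()
  at1 <- loadAtlas(d)
  at2 <- loadAtlas(d)
  expect_identical(structures(at1), structures(at2))
  expect_identical(annotation(at1), annotation(at2))

  expect_error(loadAtlas(file.path(tempdir(), "no-such-atlas")), "not found")

  ## missing annotation file
  broken <- file.path(tempdir(), "broken-atlas")
  unlink(broken, recursive = TRUE)
  dir.create(broken)
  file.copy(file.path(d, c("structures.json", "metadata.json")), broken)
  expect_error(loadAtlas(broken), "annotation.tiff")

  ## cyclic hierarchy
  cyc <- file.path(tempdir(), "cyclic-atlas")
  unlink(cyc, recursive = TRUE)
  dir.create(cyc)
  file.copy(file.path(d, c("annotation.tiff", "annotation.tiff.json",
                           "metadata.json")), cyc)
  recs <- jsonlite::fromJSON(file.path(d, "structures.json"),
                             simplifyVector = FALSE)
  recs[[1]]$parent_id <- 4L  # root now points at VISp -> cycle
  jsonlite::write_json(recs, file.path(cyc, "structures.json"),
                       auto_unbox = TRUE, null = "null")
  expect_error(loadAtlas(cyc), "root|cycle")
})

test_that("structure lookup works by acronym and id, with suggestions", {
  at <- miniAtlas()
  expect_true(is.na(getStructure(at, "root")$parent_id))
  expect_equal(getStructure(at, 4)$acronym, "VISp")
  expect_error(getStructure(at, "SCzzz"), "nearest matches")
})

test_that("ancestors and descendants traverse the hierarchy", {
  at <- miniAtlas()
  expect_equal(nrow(ancestors(at, "root")), 0L)
  expect_equal(ancestors(at, "VISp")$acronym, c("CTX", "root"))
  expect_equal(nrow(descendants(at, "VISp")), 0L)
  expect_setequal(descendants(at, "CTX")$acronym, c("VISp", "MOs"))
  expect_setequal(descendants(at, "root")$acronym,
                  c("CTX", "TH", "VISp", "MOs"))
  expect_error(ancestors(at, "nope"), "nearest matches")
})

test_that("ancestors/descendants duality holds for every node pair", {
  at <- miniAtlas()
  acrs <- structures(at)$acronym
  for (n in acrs) {
    anc <- ancestors(at, n)$acronym
    for (m in acrs) {
      expect_equal(m %in% anc, n %in% descendants(at, m)$acronym,
                   info = sprintf("pair (%s, %s)", n, m))
    }
  }
})

test_that("structureFromPoint follows the floor voxel convention", {
  at <- miniAtlas()
  res <- resolutionUm(at)
  ann <- annotation(at)
  expect_null(structureFromPoint(at, c(-1, 10, 10)))
  expect_null(structureFromPoint(at, dim(ann) * res))  # upper edge is out
  ## center of a voxel labeled 4 (VISp)
  w <- which(ann == 4L, arr.ind = TRUE)[1, ]
  center <- (w - 0.5) * res
  expect_equal(structureFromPoint(at, center)$acronym, "VISp")
  ## a point exactly on the voxel boundary belongs to the higher voxel
  v0 <- w - 1L  # 0-based index of that voxel
  boundary <- v0 * res  # lower corner: boundary with voxel v0 - 1
  lab <- ann[matrix(w, 1)]
  got <- structureFromPoint(at, boundary)
  expect_equal(if (is.null(got)) 0L else got$id, lab)
})

test_that("structureFromPoint agrees with direct voxel indexing", {
  at <- miniAtlas()
  res <- resolutionUm(at)
  ann <- annotation(at)
  st <- structures(at)
  set.seed(11)
  n <- 1000L
  pts <- cbind(runif(n, 0, dim(ann)[1] * res[1]),
               runif(n, 0, dim(ann)[2] * res[2]),
               runif(n, 0, dim(ann)[3] * res[3]))
  got <- braincanvas:::.acronymAtPoints(at, pts)
  vi <- floor(sweep(pts, 2, res, "/")) + 1L
  lab <- ann[vi]
  want <- ifelse(lab == 0L, NA_character_,
                 st$acronym[match(lab, st$id)])
  expect_identical(got, want)
})

test_that("pointInRegion resolves leaf labels through the hierarchy", {
  at <- miniAtlas()
  res <- resolutionUm(at)
  w <- which(annotation(at) == 4L, arr.ind = TRUE)[1, ]
  p <- (w - 0.5) * res
  expect_true(pointInRegion(at, p, "CTX", includeSubstructures = TRUE))
  expect_false(pointInRegion(at, p, "CTX", includeSubstructures = FALSE))
  expect_true(pointInRegion(at, p, "root", includeSubstructures = TRUE))
  expect_false(pointInRegion(at, p, "TH", includeSubstructures = TRUE))
  expect_error(pointInRegion(at, p, "XYZq"), "nearest matches")
})

test_that("region meshes match the annotation and are cached", {
  at <- miniAtlas()
  res <- resolutionUm(at)
  ann <- annotation(at)
  root <- regionMesh(at, "root")
  w <- which(ann != 0L, arr.ind = TRUE)
  loUm <- (apply(w, 2, min) - 1L) * res
  hiUm <- apply(w, 2, max) * res
  bb <- apply(vertices(root), 2, range)
  expect_true(all(abs(bb[1, ] - loUm) <= res))
  expect_true(all(abs(bb[2, ] - hiUm) <= res))
  ## root volume within 15% of labeled voxel volume
  voxVol <- sum(ann != 0L) * prod(res)
  expect_lt(abs(meshVolume(root) - voxVol) / voxVol, 0.15)
  ## CTX has no mesh file: built as the union of VISp + MOs voxels
  ctx <- regionMesh(at, "CTX")
  expect_gt(nrow(faces(ctx)), 0L)
  ctxVox <- sum(ann %in% c(4L, 5L)) * prod(res)
  expect_lt(abs(meshVolume(ctx) - ctxVox) / ctxVox, 0.15)
  ## cached object is returned as-is
  expect_identical(regionMesh(at, "CTX"), ctx)
})

test_that("a region with no mesh file and no voxels is an error", {
  at <- miniAtlas()
  st <- rbind(structures(at),
              data.frame(id = 99L, acronym = "EMPTY", name = "empty",
                         parent_id = 1L, r = 0, g = 0, b = 0,
                         mesh_available = FALSE))
  at2 <- new("BrainAtlas", name = at@name, structures = st,
             annotation = annotation(at), resolution = resolutionUm(at),
             meshDir = at@meshDir, rootAcronym = at@rootAcronym,
             cache = new.env())
  expect_error(regionMesh(at2, "EMPTY"), "empty region")
})
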