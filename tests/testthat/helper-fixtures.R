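## Shared fixtures: one standard and one small mini-atlas per test run,
## generated once and reused (the atlas bundle is deterministic).

.fixtureEnv <- new.env()

## 48 x 36 x 40 voxels at 25 um: the default study conditions
miniAtlas <- function() {
  if (is.null(.fixtureEnv$atlas)) {
    d <- file.path(tempdir(), "braincanvas-mini-atlas")
    if (!dir.exists(d)) makeMiniAtlas(d)
    .fixtureEnv$atlasDir <- d
    .fixtureEnv$atlas <- loadAtlas(d)
  }
  .fixtureEnv$atlas
}

miniAtlasDir <- function() {
  miniAtlas()
  .fixtureEnv$atlasDir
}

## coarser bundle for rendering-heavy tests
smallAtlas <- function() {
  if (is.null(.fixtureEnv$small)) {
    d <- file.path(tempdir(), "braincanvas-small-atlas")
    if (!dir.exists(d))
      makeMiniAtlas(d, fixtureSpec(gridShape = c(24L, 18L, 20L),
                                   resolution = 50))
    .fixtureEnv$smallDir <- d
    .fixtureEnv$small <- loadAtlas(d)
  }
  .fixtureEnv$small
}

smallAtlasDir <- function() {
  smallAtlas()
  .fixtureEnv$smallDir
}

## digital ball mask of the given voxel radius, centered
digitalBall <- function(r) {
  n <- 2L * r + 1L
  idx <- seq_len(n) - (n + 1) / 2
  mask <- outer(outer(idx^2, idx^2, "+"), idx^2, "+") <= r^2
  array(as.integer(mask), dim(mask))
}

## random rigid-transformed icosphere (for mesh round-trip tests)
randomMesh <- function() {
  s <- icosphere(1L)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  v <- s@vertices %*% (Rx %*% Rz) * runif(1, 5, 500) +
    matrix(runif(3, -1000, 1000), nrow(s@vertices), 3, byrow = TRUE)
  triMesh(v, s@faces)
}

## toy 3-node SWC: soma + 2-node dendrite chain
toySWC <- function(path) {
  writeLines(c("# toy neuron",
               "1 1 0 0 0 5 -1",
               "2 3 10 0 0 1 1",
               "3 3 20 0 0 1 2"), path)
  path
}

## unit-cube OBJ (8 vertices, 12 triangles), side 1
cubeOBJ <- function(path) {
  v <- expand.grid(0:1, 0:1, 0:1)
  lines <- c(sprintf("v %d %d %d", v[, 1], v[, 2], v[, 3]),
             "f 1 3 4", "f 1 4 2", "f 5 6 8", "f 5 8 7",
             "f 1 2 6", "f 1 6 5", "f 3 7 8", "f 3 8 4",
             "f 1 5 7", "f 1 7 3", "f 2 4 8", "f 2 8 6")
  writeLines(lines, path)
  path
}
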