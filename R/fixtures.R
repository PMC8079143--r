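## Synthetic test-data generators: a mini atlas bundle, labeled cells,
## neuron morphologies, streamlines and expression volumes with known
## ground truth, written in exactly the on-disk formats the loaders read.
##
## Regions are ellipsoids so analytic volumes and centroids exist; every
## leaf is a mirrored ellipsoid pair, which makes the annotation volume
## exactly left-right symmetric about the mid-sagittal plane. The
## annotation labels leaf regions only: parent membership is resolved
## through the hierarchy, as in real atlases where parents are unions of
## their children.

#' Parameters of the synthetic fixture generators
#'
#' @param seed integer random seed threaded through all sub-generators.
#' @param gridShape annotation dimensions (AP, DV, LR), each >= 8 voxels.
#' @param resolution voxel size in micrometers (scalar, isotropic).
#' @param nRegions number of leaf regions (default 3: VISp, MOs, TH).
#' @param nCells default cell count for cell generation.
#' @param nPaths default streamline count.
#' @return A validated list of fixture parameters.
#' @export
fixtureSpec <- function(seed = 1L, gridShape = c(48L, 36L, 40L),
                        resolution = 25, nRegions = 3L, nCells = 1000L,
                        nPaths = 10L) {
  if (any(gridShape < 8L)) stop("gridShape components must be >= 8")
  if (any(c(nRegions, nCells, nPaths) < 0L) || nRegions < 1L)
    stop("counts must be positive")
  if (resolution <= 0) stop("resolution must be positive")
  list(seed = as.integer(seed), gridShape = as.integer(gridShape),
       resolution = as.numeric(resolution), nRegions = as.integer(nRegions),
       nCells = as.integer(nCells), nPaths = as.integer(nPaths))
}

## ellipsoid mask over voxel centers (voxel units)
.ellipsoidMask <- function(g, center, semi) {
  ci <- (seq_len(g[1]) - 0.5 - center[1]) / semi[1]
  cj <- (seq_len(g[2]) - 0.5 - center[2]) / semi[2]
  ck <- (seq_len(g[3]) - 0.5 - center[3]) / semi[3]
  outer(outer(ci^2, cj^2, "+"), ck^2, "+") <= 1
}

#' Generate a synthetic mini-atlas bundle on disk
#'
#' Writes a complete atlas directory loadable by [loadAtlas()]: a
#' structures.json hierarchy (root -> CTX -> {VISp, MOs}; TH and any
#' further leaves directly under root), a leaf-labeled annotation TIFF
#' with exact left-right mirror symmetry, metadata, and OBJ meshes for
#' the root and every leaf (CTX intentionally ships without a mesh file
#' so building parent meshes from the annotation stays exercised).
#'
#' @param outDir output directory (created).
#' @param spec a [fixtureSpec()].
#' @return \code{outDir}, invisibly.
#' @export
makeMiniAtlas <- function(outDir, spec = fixtureSpec()) {
  g <- spec$gridShape
  res <- rep(spec$resolution, 3L)
  cen <- g / 2
  rootMask <- .ellipsoidMask(g, cen, 0.45 * g)
  leafNames <- c("VISp", "MOs", "TH",
                 if (spec$nRegions > 3L)
                   paste0("RG", seq_len(spec$nRegions - 3L) + 3L))
  leafNames <- leafNames[seq_len(spec$nRegions)]
  ## ids follow the hierarchy listing order: root 1, CTX 2, TH 3, VISp 4,
  ## MOs 5, further leaves 6, 7, ...
  leafIds <- vapply(leafNames, function(nm)
    switch(nm, VISp = 4L, MOs = 5L, TH = 3L,
           as.integer(sub("^RG", "", nm)) + 2L), integer(1))
  palette <- rbind(c(8, 133, 140), c(31, 157, 90), c(255, 112, 128),
                   c(148, 103, 189), c(140, 86, 75), c(227, 119, 194))
  ann <- array(0L, g)
  for (l in seq_along(leafNames)) {
    th <- 2 * pi * (l - 1) / length(leafNames)
    ci <- cen[1] + 0.26 * g[1] * cos(th)
    cj <- cen[2] + 0.26 * g[2] * sin(th)
    ckOff <- 0.22 * g[3]
    semi <- pmax(0.11 * g, 2.2)
    m <- (.ellipsoidMask(g, c(ci, cj, cen[3] + ckOff), semi) |
          .ellipsoidMask(g, c(ci, cj, cen[3] - ckOff), semi)) & rootMask
    if (!any(m))
      stop("generation error: a region voxelized to nothing; enlarge gridShape")
    if (any(ann[m] != 0L))
      stop("generation error: regions overlap; reduce nRegions")
    ann[m] <- leafIds[l]
  }
  dir.create(file.path(outDir, "meshes"), recursive = TRUE,
             showWarnings = FALSE)
  structs <- list(
    list(id = 1L, acronym = "root", name = "whole brain",
         parent_id = NULL, rgb = c(211L, 211L, 211L)),
    list(id = 2L, acronym = "CTX", name = "cortex",
         parent_id = 1L, rgb = c(112L, 255L, 112L)))
  ord <- order(leafIds)
  for (l in ord) {
    parent <- if (leafNames[l] %in% c("VISp", "MOs")) 2L else 1L
    structs[[length(structs) + 1L]] <-
      list(id = leafIds[l], acronym = leafNames[l],
           name = paste("synthetic region", leafNames[l]),
           parent_id = parent,
           rgb = as.integer(palette[(l - 1L) %% nrow(palette) + 1L, ]))
  }
  jsonlite::write_json(structs, file.path(outDir, "structures.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(list(name = "braincanvas-mini", resolution = res),
                       file.path(outDir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  writeVolumeTIFF(ann, file.path(outDir, "annotation.tiff"),
                  resolution = res)
  ## meshes for root (union of all labels) and each leaf
  rootMesh <- labelIsosurface(ann, labels = leafIds, resolution = res)
  writeMeshFile(rootMesh, file.path(outDir, "meshes", "root.obj"))
  for (l in seq_along(leafNames)) {
    m <- labelIsosurface(ann, labels = leafIds[l], resolution = res)
    writeMeshFile(m, file.path(outDir, "meshes",
                               paste0(leafNames[l], ".obj")))
  }
  invisible(outDir)
}

#' Sample synthetic labeled cells inside a region
#'
#' Uniform sampling over the region's voxel mask (own label plus all
#' descendants): a random labeled voxel, then a uniform position within
#' it. Every returned point therefore satisfies
#' \code{pointInRegion(..., includeSubstructures = TRUE)}.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param acronym region acronym.
#' @param n number of cells.
#' @param seed random seed.
#' @return A \linkS4class{BrainPoints} with n coordinates.
#' @export
makeSyntheticCells <- function(atlas, acronym, n, seed = 1L) {
  stopifnot(is(atlas, "BrainAtlas"))
  node <- .structureRow(atlas, acronym)
  ids <- c(node$id, descendants(atlas, node$acronym)$id)
  vox <- which(array(atlas@annotation %in% ids, dim(atlas@annotation)))
  if (!length(vox))
    stop(sprintf("empty region: '%s' has no labeled voxels", acronym))
  if (n == 0L) return(brainPoints(matrix(numeric(0), 0, 3)))
  res <- atlas@resolution
  .withSeed(seed, {
    pick <- vox[sample.int(length(vox), n, replace = TRUE)]
    idx0 <- arrayInd(pick, dim(atlas@annotation)) - 1L  # 0-based voxel
    u <- matrix(stats::runif(3L * n), n, 3)
    brainPoints(sweep(idx0 + u, 2, res, "*"))
  })
}

#' Generate a synthetic neuron morphology as an SWC file
#'
#' A random binary-branching tree: one soma node with a single primary
#' neurite; each branch event splits an existing tip into two daughter
#' chains, so the parsed tree has exactly \code{nBranchPoints} nodes
#' with more than one child.
#'
#' @param path output .swc path.
#' @param seed random seed.
#' @param nBranchPoints number of branch events (>= 0).
#' @param somaPosition soma coordinate, micrometers.
#' @param somaRadius soma radius (default 8).
#' @param segmentNodes nodes per unbranched chain (default 5).
#' @param stepUm spatial step between nodes (default 12).
#' @return \code{path}, invisibly.
#' @export
makeSyntheticNeuron <- function(path, seed = 1L, nBranchPoints = 3L,
                                somaPosition = c(0, 0, 0), somaRadius = 8,
                                segmentNodes = 5L, stepUm = 12) {
  stopifnot(nBranchPoints >= 0L)
  .withSeed(seed, {
    nodes <- data.frame(sample_id = 1L, type = 1L,
                        x = somaPosition[1], y = somaPosition[2],
                        z = somaPosition[3], radius = somaRadius,
                        parent_id = -1L)
    nextId <- 2L
    growChain <- function(fromId, fromPos, dir) {
      for (s in seq_len(segmentNodes)) {
        dir <- .normalize(dir + 0.25 * stats::rnorm(3))
        fromPos <- fromPos + stepUm * dir
        nodes[nrow(nodes) + 1L, ] <<- list(nextId, 3L, fromPos[1],
                                           fromPos[2], fromPos[3], 1.2,
                                           fromId)
        fromId <- nextId
        nextId <<- nextId + 1L
      }
      list(id = fromId, pos = fromPos, dir = dir)
    }
    tip <- growChain(1L, somaPosition, .normalize(stats::rnorm(3)))
    tips <- list(tip)
    for (b in seq_len(nBranchPoints)) {
      pick <- sample.int(length(tips), 1L)
      t0 <- tips[[pick]]
      tips <- tips[-pick]
      for (d in 1:2) {
        dir <- .normalize(t0$dir + 0.8 * stats::rnorm(3))
        tips[[length(tips) + 1L]] <- growChain(t0$id, t0$pos, dir)
      }
    }
    writeSWC(new("NeuronMorphology", nodes = nodes), path)
  })
  invisible(path)
}

#' Generate synthetic streamlines starting inside a region
#'
#' Smooth random-walk polylines whose first point is always inside the
#' source region; written as a streamlines JSON file.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param sourceAcronym seed region acronym.
#' @param nPaths number of paths.
#' @param path output .json path.
#' @param seed random seed.
#' @param nSteps points per path (default 20).
#' @return \code{path}, invisibly.
#' @export
makeSyntheticStreamlines <- function(atlas, sourceAcronym, nPaths, path,
                                     seed = 1L, nSteps = 20L) {
  starts <- makeSyntheticCells(atlas, sourceAcronym, nPaths, seed = seed)
  step <- mean(atlas@resolution) * 0.8
  .withSeed(seed + 1L, {
    paths <- lapply(seq_len(nPaths), function(i) {
      p <- starts@coordinates[i, ]
      dir <- .normalize(stats::rnorm(3))
      out <- matrix(0, nSteps, 3)
      out[1, ] <- p
      for (s in 2:nSteps) {
        dir <- .normalize(dir + 0.3 * stats::rnorm(3))
        p <- p + step * dir
        out[s, ] <- p
      }
      out
    })
    writeStreamlines(new("Streamlines", paths = paths), path)
  })
  invisible(path)
}

#' Generate a synthetic expression volume as a TIFF stack
#'
#' Gaussian background (mean 10) everywhere and elevated values
#' (mean 100) inside the hot region, so thresholding at the midpoint
#' (55) recovers the hot-region mask almost exactly.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param hotAcronym region with elevated expression.
#' @param path output .tiff path (a resolution sidecar is written too).
#' @param seed random seed.
#' @param hotMean,bgMean,sd generator parameters.
#' @return \code{path}, invisibly.
#' @export
makeExpressionVolume <- function(atlas, hotAcronym, path, seed = 1L,
                                 hotMean = 100, bgMean = 10, sd = 6) {
  stopifnot(is(atlas, "BrainAtlas"))
  node <- .structureRow(atlas, hotAcronym)
  ids <- c(node$id, descendants(atlas, node$acronym)$id)
  hot <- array(atlas@annotation %in% ids, dim(atlas@annotation))
  if (!any(hot))
    stop(sprintf("empty region: '%s' has no labeled voxels", hotAcronym))
  .withSeed(seed, {
    vals <- array(stats::rnorm(length(hot), bgMean, sd), dim(hot))
    vals[hot] <- stats::rnorm(sum(hot), hotMean, sd)
    vals <- round(pmin(pmax(vals, 0), 65535))
    writeVolumeTIFF(volumeGrid(vals, atlas@resolution), path)
  })
  invisible(path)
}
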