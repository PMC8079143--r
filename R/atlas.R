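## Atlas bundle loading, hierarchy queries and spatial queries.
##
## On-disk bundle layout (all plain files, no downloads):
##   structures.json   array of {id, acronym, name, parent_id, rgb}
##   annotation.tiff   uint16 label stack, pages along the AP axis
##   metadata.json     {name, resolution: [ap, dv, lr] um}
##   meshes/<acronym>.obj   optional per-region meshes
##
## Physical axes are (AP, DV, LR) in micrometers, matching voxel indices
## (i, j, k); voxel i spans [i*res, (i+1)*res) so points map to voxels by
## floor division (a point exactly on a boundary belongs to the
## higher-index voxel).

#' Load a brain atlas bundle from a directory
#'
#' Reads the structure hierarchy, annotation label volume, metadata and
#' mesh store, and validates all tree invariants (unique ids/acronyms,
#' single root, acyclic parent chains, annotation labels present in the
#' tree). Stored region meshes are checked to lie inside the annotation
#' bounding box within one voxel.
#'
#' @param path atlas directory.
#' @return A validated \linkS4class{BrainAtlas}.
#' @seealso [makeMiniAtlas()] to generate a synthetic bundle.
#' @export
loadAtlas <- function(path) {
  if (!dir.exists(path)) stop(sprintf("atlas directory not found: %s", path))
  need <- c("structures.json", "annotation.tiff", "metadata.json")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop(sprintf("atlas load error: missing file '%s' in %s", f, path))
  meta <- jsonlite::fromJSON(file.path(path, "metadata.json"))
  recs <- jsonlite::fromJSON(file.path(path, "structures.json"),
                             simplifyVector = FALSE)
  meshDir <- file.path(path, "meshes")
  st <- do.call(rbind, lapply(recs, function(r) {
    rgb <- as.integer(unlist(r$rgb))
    data.frame(id = as.integer(r$id), acronym = as.character(r$acronym),
               name = as.character(r$name),
               parent_id = if (is.null(r$parent_id)) NA_integer_
                           else as.integer(r$parent_id),
               r = rgb[1], g = rgb[2], b = rgb[3],
               mesh_available = file.exists(
                 file.path(meshDir, paste0(r$acronym, ".obj"))))
  }))
  vol <- readVolumeTIFF(file.path(path, "annotation.tiff"),
                        resolution = meta$resolution)
  ann <- vol@values
  storage.mode(ann) <- "integer"
  rootAcr <- st$acronym[is.na(st$parent_id)]
  if (length(rootAcr) != 1L)
    stop(sprintf("atlas validation error: expected exactly 1 root, found %d",
                 length(rootAcr)))
  atlas <- new("BrainAtlas", name = as.character(meta$name),
               structures = st, annotation = ann,
               resolution = as.numeric(meta$resolution),
               meshDir = meshDir, rootAcronym = rootAcr,
               cache = new.env(parent = emptyenv()))
  ## stored meshes must sit inside the annotation box (one voxel slack)
  ext <- dim(ann) * atlas@resolution
  tol <- max(atlas@resolution)
  for (acr in st$acronym[st$mesh_available]) {
    m <- readMeshFile(file.path(meshDir, paste0(acr, ".obj")))
    if (!nrow(m@vertices)) next
    bb <- .bbox(m@vertices)
    if (any(bb[1, ] < -tol) || any(bb[2, ] > ext + tol))
      stop(sprintf(
        "atlas validation error: mesh '%s' exceeds the annotation bounds",
        acr))
  }
  atlas
}

.structureRow <- function(atlas, key, what = "structure") {
  st <- atlas@structures
  i <- if (is.numeric(key)) match(as.integer(key), st$id)
       else match(as.character(key), st$acronym)
  if (is.na(i)) .unknownKeyStop(key, st$acronym, what)
  st[i, , drop = FALSE]
}

#' Look up a structure by acronym or id
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param key acronym (character) or structure id (numeric).
#' @return One-row data.frame describing the structure.
#' @examples \dontrun{getStructure(atlas, "VISp"); getStructure(atlas, 4)}
#' @export
getStructure <- function(atlas, key) {
  stopifnot(is(atlas, "BrainAtlas"))
  row <- .structureRow(atlas, key)
  rownames(row) <- NULL
  row
}

#' Ancestors of a structure, from immediate parent up to the root
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param acronym structure acronym.
#' @return data.frame of ancestor structures (0 rows for the root).
#' @export
ancestors <- function(atlas, acronym) {
  stopifnot(is(atlas, "BrainAtlas"))
  st <- atlas@structures
  node <- .structureRow(atlas, acronym)
  out <- integer(0)
  p <- node$parent_id
  while (!is.na(p)) {
    i <- match(p, st$id)
    out <- c(out, i)
    p <- st$parent_id[i]
  }
  res <- st[out, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Descendants of a structure (all substructures, query excluded)
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param acronym structure acronym.
#' @return data.frame of descendant structures (0 rows for a leaf).
#' @export
descendants <- function(atlas, acronym) {
  stopifnot(is(atlas, "BrainAtlas"))
  st <- atlas@structures
  node <- .structureRow(atlas, acronym)
  frontier <- node$id
  out <- integer(0)
  repeat {
    kids <- which(st$parent_id %in% frontier)
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- st$id[kids]
  }
  res <- st[sort(out), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## vectorized: acronym (or NA for outside-brain / off-grid) per point row
.acronymAtPoints <- function(atlas, coords) {
  coords <- if (is.matrix(coords)) coords else matrix(coords, ncol = 3)
  res <- atlas@resolution
  d <- dim(atlas@annotation)
  vi <- floor(sweep(coords, 2, res, "/"))  # 0-based voxel indices
  ok <- vi[, 1] >= 0 & vi[, 1] < d[1] &
        vi[, 2] >= 0 & vi[, 2] < d[2] &
        vi[, 3] >= 0 & vi[, 3] < d[3]
  lab <- integer(nrow(coords))
  if (any(ok)) {
    flat <- 1 + vi[ok, 1] + d[1] * (vi[ok, 2] + d[2] * vi[ok, 3])
    lab[ok] <- atlas@annotation[flat]
  }
  st <- atlas@structures
  out <- rep(NA_character_, nrow(coords))
  hit <- ok & lab != 0L
  out[hit] <- st$acronym[match(lab[hit], st$id)]
  out
}

#' Structure containing a physical point
#'
#' Maps the point to its voxel by floor(coordinate / resolution) per axis
#' and returns the structure labeled there. Points outside the grid or in
#' unlabeled (label 0) voxels are "outside": the function returns NULL.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param point length-3 micrometer coordinate (AP, DV, LR).
#' @return One-row structure data.frame, or NULL when outside the brain.
#' @export
structureFromPoint <- function(atlas, point) {
  stopifnot(is(atlas, "BrainAtlas"))
  acr <- .acronymAtPoints(atlas, matrix(as.numeric(point), 1, 3))
  if (is.na(acr)) return(NULL)
  getStructure(atlas, acr)
}

#' Is a point inside a brain region?
#'
#' TRUE when the structure labeled at the point's voxel is the query
#' region itself or (with \code{includeSubstructures}) any of its
#' descendants. Annotation volumes typically label leaf regions only, so
#' membership in a parent region is resolved through the hierarchy.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param point length-3 coordinate or N x 3 matrix (micrometers).
#' @param acronym region acronym.
#' @param includeSubstructures count descendants as inside (default TRUE).
#' @return Logical vector with one value per point.
#' @export
pointInRegion <- function(atlas, point, acronym,
                          includeSubstructures = TRUE) {
  stopifnot(is(atlas, "BrainAtlas"))
  node <- .structureRow(atlas, acronym)
  accept <- node$acronym
  if (includeSubstructures)
    accept <- c(accept, descendants(atlas, acronym)$acronym)
  hits <- .acronymAtPoints(atlas,
                           if (is.matrix(point)) point
                           else matrix(as.numeric(point), ncol = 3))
  !is.na(hits) & hits %in% accept
}

#' Triangle mesh of a brain region
#'
#' Returns the stored mesh when the bundle ships one; otherwise builds
#' the surface by isosurfacing the union of the region's own annotation
#' label and all descendant labels (parents are unions of their
#' children). Results are cached on the atlas; reload the atlas to
#' invalidate.
#'
#' @param atlas a \linkS4class{BrainAtlas}.
#' @param acronym region acronym.
#' @param smoothing Laplacian iterations applied when building from the
#'   annotation (default 0).
#' @return A \linkS4class{TriMesh} in micrometers.
#' @export
regionMesh <- function(atlas, acronym, smoothing = 0L) {
  stopifnot(is(atlas, "BrainAtlas"))
  node <- .structureRow(atlas, acronym)
  acr <- node$acronym
  cached <- atlas@cache[[acr]]
  if (!is.null(cached)) return(cached)
  meshFile <- file.path(atlas@meshDir, paste0(acr, ".obj"))
  if (node$mesh_available && file.exists(meshFile)) {
    m <- readMeshFile(meshFile)
  } else {
    ids <- c(node$id, descendants(atlas, acr)$id)
    present <- ids[ids %in% unique(as.vector(atlas@annotation))]
    if (!length(present))
      stop(sprintf(
        "empty region: '%s' has no mesh file and no labeled voxels", acr))
    m <- labelIsosurface(atlas, labels = present, smoothing = smoothing)
  }
  atlas@cache[[acr]] <- m
  m
}
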