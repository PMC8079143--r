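## Internal helpers: colors, errors, small geometry utilities.

#' Normalize a color specification to "#rrggbb"
#'
#' Accepts R color names (see grDevices::colors()), hex "#rgb"/"#rrggbb",
#' or an RGB triple of 0-255 integers.
#'
#' @param color a color name, hex string, or length-3 numeric 0-255.
#' @return Lower-case "#rrggbb" string.
#' @examples
#' normalizeColor("salmon")
#' normalizeColor(c(255, 0, 0))
#' @export
normalizeColor <- function(color) {
  if (is.numeric(color) && length(color) == 3L) {
    if (any(color < 0 | color > 255)) stop("RGB components must be in 0..255")
    return(tolower(grDevices::rgb(color[1], color[2], color[3],
                                  maxColorValue = 255)))
  }
  if (!is.character(color) || length(color) != 1L)
    stop("color must be a single name, hex string, or RGB triple")
  rgbv <- tryCatch(grDevices::col2rgb(color),
                   error = function(e) NULL)
  if (is.null(rgbv)) {
    near <- utils::head(agrep(color, grDevices::colors(), value = TRUE,
                              max.distance = 0.3), 3L)
    stop(sprintf("unknown color '%s'%s", color,
                 if (length(near)) paste0("; did you mean: ",
                                          paste(near, collapse = ", "))
                 else ""))
  }
  tolower(grDevices::rgb(rgbv[1], rgbv[2], rgbv[3], maxColorValue = 255))
}

## hex -> numeric RGB in [0, 1]
.colorToUnit <- function(hex) as.numeric(grDevices::col2rgb(hex)) / 255

## lookup-error helper with nearest-acronym suggestions
.unknownKeyStop <- function(key, known, what = "acronym") {
  near <- character(0)
  if (is.character(key))
    near <- utils::head(agrep(key, known, value = TRUE, max.distance = 0.4), 5L)
  if (!length(near)) near <- utils::head(known, 5L)
  stop(sprintf("unknown %s '%s'; nearest matches: %s", what, key,
               paste(near, collapse = ", ")), call. = FALSE)
}

## bounding box of an n x 3 matrix: 2 x 3 (min row, max row)
.bbox <- function(coords) {
  if (!nrow(coords)) return(matrix(NA_real_, 2, 3))
  apply(coords, 2, range)
}

.bboxCenter <- function(coords) colMeans(.bbox(coords))

.bboxDiag <- function(coords) {
  bb <- .bbox(coords)
  sqrt(sum((bb[2, ] - bb[1, ])^2))
}

## cross product
.cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.normalize <- function(v) {
  len <- sqrt(sum(v^2))
  if (len == 0) stop("cannot normalize a zero vector")
  v / len
}

## merge several TriMesh objects into one (vertex offsets adjusted)
#' Merge meshes into a single TriMesh
#' @param meshes list of \linkS4class{TriMesh} objects.
#' @return One \linkS4class{TriMesh} holding all vertices and faces.
#' @export
mergeMeshes <- function(meshes) {
  meshes <- Filter(function(m) nrow(m@vertices) > 0, meshes)
  if (!length(meshes)) return(emptyMesh())
  vs <- lapply(meshes, function(m) m@vertices)
  fs <- vector("list", length(meshes))
  off <- 0L
  for (i in seq_along(meshes)) {
    fs[[i]] <- meshes[[i]]@faces + off
    off <- off + nrow(meshes[[i]]@vertices)
  }
  triMesh(do.call(rbind, vs), do.call(rbind, fs))
}

## number of connected components of a mesh (vertex connectivity)
.meshComponents <- function(mesh) {
  nv <- nrow(mesh@vertices)
  if (!nv) return(0L)
  parent <- seq_len(nv)
  findp <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  f <- mesh@faces
  for (k in seq_len(nrow(f))) {
    a <- findp(f[k, 1]); b <- findp(f[k, 2]); d <- findp(f[k, 3])
    parent[b] <- a; parent[findp(d)] <- a
  }
  length(unique(vapply(seq_len(nv), findp, integer(1))))
}

## deterministic local RNG: evaluate expr with a private seed, restoring state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
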