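#' TriMesh: a triangle surface mesh
#'
#' Vertices are physical coordinates in micrometers; faces are 1-based
#' triangles. The empty mesh (0 vertices, 0 faces) is a valid value and is
#' what slicing returns when everything falls on the discarded side.
#'
#' @slot vertices numeric V x 3 matrix.
#' @slot faces integer F x 3 matrix of vertex indices in 1..V.
#' @exportClass TriMesh
setClass("TriMesh",
  representation(vertices = "matrix", faces = "matrix"),
  prototype(vertices = matrix(numeric(0), 0, 3),
            faces = matrix(integer(0), 0, 3)))

setValidity("TriMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must have 3 columns")
  if (ncol(f) != 3L) return("faces must have 3 columns")
  if (nrow(v) > 0 && !is.numeric(v)) return("vertices must be numeric")
  if (nrow(f) > 0) {
    if (any(f < 1L) || any(f > nrow(v)))
      return("face indices out of range [1, V]")
    if (any(f[, 1] == f[, 2] | f[, 1] == f[, 3] | f[, 2] == f[, 3]))
      return("degenerate face (repeated vertex index)")
  }
  TRUE
})

#' Construct a TriMesh
#'
#' @param vertices numeric V x 3 matrix (micrometers).
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @return A \linkS4class{TriMesh}.
#' @examples
#' m <- triMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)), rbind(c(1,2,3)))
#' nrow(vertices(m))
#' @export
triMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  new("TriMesh", vertices = vertices, faces = faces)
}

#' The empty mesh
#' @return A \linkS4class{TriMesh} with 0 vertices and 0 faces.
#' @export
emptyMesh <- function() new("TriMesh")

#' Is a mesh empty?
#' @param mesh a \linkS4class{TriMesh}.
#' @return TRUE when the mesh has no faces.
#' @export
isEmptyMesh <- function(mesh) nrow(mesh@faces) == 0L

#' Plane: an oriented cutting plane
#'
#' @slot origin numeric length-3 point on the plane (micrometers).
#' @slot normal numeric length-3 unit normal.
#' @exportClass Plane
setClass("Plane", representation(origin = "numeric", normal = "numeric"))

setValidity("Plane", function(object) {
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (length(object@normal) != 3L) return("normal must have length 3")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be a unit vector (|n| = 1 within 1e-9)")
  TRUE
})

#' Construct a Plane
#'
#' The normal is normalized to unit length. For \code{sliceMesh} the
#' convention is: keep = "below" retains points p with
#' (p - origin) . normal <= 0, i.e. the normal points toward the
#' discarded half-space.
#'
#' @param origin point on the plane (length-3, micrometers).
#' @param normal plane normal (length-3, any nonzero length).
#' @return A \linkS4class{Plane}.
#' @examples
#' pl <- plane(c(0, 0, 0), c(1, 0, 0))
#' @export
plane <- function(origin, normal) {
  n <- as.numeric(normal)
  len <- sqrt(sum(n^2))
  if (!is.finite(len) || len == 0) stop("plane normal must be nonzero")
  new("Plane", origin = as.numeric(origin), normal = n / len)
}

#' BrainAtlas: structure hierarchy + annotation volume + mesh store
#'
#' Physical coordinates are micrometers on axes (AP, DV, LR) matching voxel
#' indices (i, j, k); voxel i spans [i*res, (i+1)*res) so points map to
#' voxels by floor division.
#'
#' @slot name atlas name.
#' @slot structures data.frame: id, acronym, name, parent_id (NA for the
#'   root), r, g, b (0-255), mesh_available.
#' @slot annotation 3D integer array of structure ids (0 = outside brain).
#' @slot resolution numeric length-3 voxel size in micrometers per axis.
#' @slot meshDir directory holding per-region OBJ files.
#' @slot rootAcronym acronym of the root node.
#' @slot cache environment caching built region meshes by acronym.
#' @exportClass BrainAtlas
setClass("BrainAtlas",
  representation(name = "character", structures = "data.frame",
                 annotation = "array", resolution = "numeric",
                 meshDir = "character", rootAcronym = "character",
                 cache = "environment"))

setValidity("BrainAtlas", function(object) {
  st <- object@structures
  need <- c("id", "acronym", "name", "parent_id", "r", "g", "b",
            "mesh_available")
  if (!all(need %in% names(st)))
    return(paste("structures missing columns:",
                 paste(setdiff(need, names(st)), collapse = ", ")))
  if (anyDuplicated(st$id)) return("duplicate structure id")
  if (anyDuplicated(st$acronym)) return("duplicate structure acronym")
  nroot <- sum(is.na(st$parent_id))
  if (nroot != 1L) return(sprintf("expected exactly 1 root, found %d", nroot))
  ## every parent chain must terminate at the root (no cycles, no orphans)
  idx <- match(st$parent_id, st$id)
  if (any(!is.na(st$parent_id) & is.na(idx)))
    return("parent_id references an unknown structure id")
  for (i in seq_len(nrow(st))) {
    seen <- integer(0); j <- i
    while (!is.na(st$parent_id[j])) {
      if (j %in% seen) return("cycle in structure hierarchy")
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  root <- st$acronym[is.na(st$parent_id)]
  if (!identical(object@rootAcronym, root))
    return("rootAcronym does not resolve to the root node")
  if (length(dim(object@annotation)) != 3L)
    return("annotation must be a 3D array")
  labs <- unique(as.vector(object@annotation))
  labs <- labs[labs != 0L]
  if (!all(labs %in% st$id))
    return("annotation contains labels absent from the structure tree")
  if (length(object@resolution) != 3L || any(object@resolution <= 0))
    return("resolution must be 3 strictly positive values")
  rgbcols <- c(st$r, st$g, st$b)
  if (any(rgbcols < 0 | rgbcols > 255)) return("rgb values must be in 0..255")
  TRUE
})

#' NeuronMorphology: an SWC node tree
#'
#' @slot nodes data.frame with columns sample_id, type (SWC type code:
#'   1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite; larger codes
#'   allowed), x, y, z (micrometers), radius (micrometers), parent_id
#'   (-1 for roots).
#' @exportClass NeuronMorphology
setClass("NeuronMorphology", representation(nodes = "data.frame"))

setValidity("NeuronMorphology", function(object) {
  nd <- object@nodes
  need <- c("sample_id", "type", "x", "y", "z", "radius", "parent_id")
  if (!all(need %in% names(nd)))
    return(paste("nodes missing columns:",
                 paste(setdiff(need, names(nd)), collapse = ", ")))
  if (nrow(nd) == 0L) return("morphology has no nodes")
  if (anyDuplicated(nd$sample_id)) return("duplicate sample_id")
  if (!any(nd$parent_id == -1L)) return("no root node (parent_id == -1)")
  if (any(nd$radius <= 0)) return("radii must be strictly positive")
  ## parents must be defined on an earlier line (standard SWC ordering)
  for (i in seq_len(nrow(nd))) {
    p <- nd$parent_id[i]
    if (p != -1L && !(p %in% nd$sample_id[seq_len(i - 1L)]))
      return(sprintf("node %d references parent %d not defined earlier",
                     nd$sample_id[i], p))
  }
  TRUE
})

#' Streamlines: polyline paths in atlas space
#'
#' @slot paths list of numeric n x 3 matrices (micrometers), each with
#'   at least 2 points.
#' @slot intensity optional per-path scalar (length 0 or length(paths)).
#' @slot nDropped number of too-short paths dropped at load time.
#' @exportClass Streamlines
setClass("Streamlines",
  representation(paths = "list", intensity = "numeric",
                 nDropped = "integer"),
  prototype(paths = list(), intensity = numeric(0), nDropped = 0L))

setValidity("Streamlines", function(object) {
  for (p in object@paths) {
    if (!is.matrix(p) || ncol(p) != 3L) return("each path must be an n x 3 matrix")
    if (nrow(p) < 2L) return("each path needs at least 2 points")
  }
  if (length(object@intensity) &&
      length(object@intensity) != length(object@paths))
    return("intensity must be empty or one value per path")
  TRUE
})

#' BrainPoints: labeled point coordinates
#'
#' @slot coordinates numeric N x 3 matrix (micrometers).
#' @slot labels optional character labels (length 0 or N).
#' @slot nDropped rows dropped at load time for non-finite values.
#' @exportClass BrainPoints
setClass("BrainPoints",
  representation(coordinates = "matrix", labels = "character",
                 nDropped = "integer"),
  prototype(coordinates = matrix(numeric(0), 0, 3), labels = character(0),
            nDropped = 0L))

setValidity("BrainPoints", function(object) {
  if (ncol(object@coordinates) != 3L) return("coordinates must be N x 3")
  if (nrow(object@coordinates) && !all(is.finite(object@coordinates)))
    return("coordinates must all be finite")
  if (length(object@labels) &&
      length(object@labels) != nrow(object@coordinates))
    return("labels must be empty or one per point")
  TRUE
})

#' Construct BrainPoints from a coordinate matrix
#' @param coordinates numeric N x 3 matrix.
#' @param labels optional character labels.
#' @return A \linkS4class{BrainPoints}.
#' @export
brainPoints <- function(coordinates, labels = character(0)) {
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  dimnames(coordinates) <- NULL
  new("BrainPoints", coordinates = coordinates,
      labels = as.character(labels), nDropped = 0L)
}

#' VolumeGrid: a scalar 3D image with physical spacing
#'
#' @slot values 3D numeric array.
#' @slot resolution micrometers per voxel per axis (strictly positive).
#' @slot origin physical offset of voxel (0,0,0) corner, micrometers.
#' @exportClass VolumeGrid
setClass("VolumeGrid",
  representation(values = "array", resolution = "numeric",
                 origin = "numeric"))

setValidity("VolumeGrid", function(object) {
  if (length(dim(object@values)) != 3L) return("values must be a 3D array")
  if (length(object@resolution) != 3L || any(object@resolution <= 0))
    return("resolution must be 3 strictly positive values")
  if (length(object@origin) != 3L) return("origin must have length 3")
  TRUE
})

#' Construct a VolumeGrid
#' @param values 3D numeric array.
#' @param resolution voxel size, scalar or length-3 (micrometers).
#' @param origin physical offset, default c(0,0,0).
#' @return A \linkS4class{VolumeGrid}.
#' @export
volumeGrid <- function(values, resolution, origin = c(0, 0, 0)) {
  if (length(resolution) == 1L) resolution <- rep(resolution, 3L)
  new("VolumeGrid", values = values, resolution = as.numeric(resolution),
      origin = as.numeric(origin))
}

#' ActorStyle: visual style of a scene actor
#'
#' @slot color hex color string ("#rrggbb").
#' @slot alpha opacity in [0, 1].
#' @slot lineWidth line width in pixels (wireframe/path rendering).
#' @slot visible logical.
#' @exportClass ActorStyle
setClass("ActorStyle",
  representation(color = "character", alpha = "numeric",
                 lineWidth = "numeric", visible = "logical"),
  prototype(color = "#aaaaaa", alpha = 1, lineWidth = 1, visible = TRUE))

setValidity("ActorStyle", function(object) {
  if (length(object@alpha) != 1L || is.na(object@alpha) ||
      object@alpha < 0 || object@alpha > 1)
    return("alpha must be a single value in [0, 1]")
  if (!grepl("^#[0-9a-f]{6}$", object@color))
    return("color must be normalized hex '#rrggbb'")
  if (object@lineWidth <= 0) return("lineWidth must be positive")
  TRUE
})

.ACTOR_KINDS <- c("region", "points", "neuron_part", "streamlines",
                  "volume", "user_mesh", "probe")

#' SceneActor: a renderable object with identity and style
#'
#' @slot name unique (within a scene) actor name.
#' @slot kind one of region, points, neuron_part, streamlines, volume,
#'   user_mesh, probe.
#' @slot mesh the actor's \linkS4class{TriMesh}.
#' @slot style an \linkS4class{ActorStyle}.
#' @slot source provenance (file path or atlas acronym).
#' @exportClass SceneActor
setClass("SceneActor",
  representation(name = "character", kind = "character", mesh = "TriMesh",
                 style = "ActorStyle", source = "character"))

setValidity("SceneActor", function(object) {
  if (!object@kind %in% .ACTOR_KINDS)
    return(paste("kind must be one of:", paste(.ACTOR_KINDS, collapse = ", ")))
  if (length(object@name) != 1L || !nzchar(object@name))
    return("name must be a non-empty string")
  TRUE
})

#' CameraPose: position, aim and orientation of the camera
#'
#' @slot position camera location (micrometers).
#' @slot focalPoint point the camera looks at.
#' @slot viewup unit up-vector of the image plane.
#' @slot zoom positive magnification factor.
#' @exportClass CameraPose
setClass("CameraPose",
  representation(position = "numeric", focalPoint = "numeric",
                 viewup = "numeric", zoom = "numeric"))

setValidity("CameraPose", function(object) {
  if (length(object@position) != 3L || length(object@focalPoint) != 3L ||
      length(object@viewup) != 3L)
    return("position, focalPoint and viewup must have length 3")
  if (all(object@position == object@focalPoint))
    return("camera position must differ from focal point")
  if (abs(sqrt(sum(object@viewup^2)) - 1) > 1e-9)
    return("viewup must be a unit vector")
  if (length(object@zoom) != 1L || object@zoom <= 0)
    return("zoom must be a positive scalar")
  TRUE
})

#' Construct a CameraPose
#'
#' @param position camera location (length-3, micrometers).
#' @param focalPoint point the camera looks at.
#' @param viewup up direction (normalized internally).
#' @param zoom positive magnification, default 1.
#' @return A \linkS4class{CameraPose}.
#' @export
cameraPose <- function(position, focalPoint, viewup = c(0, -1, 0), zoom = 1) {
  vu <- as.numeric(viewup)
  vu <- vu / sqrt(sum(vu^2))
  new("CameraPose", position = as.numeric(position),
      focalPoint = as.numeric(focalPoint), viewup = vu,
      zoom = as.numeric(zoom))
}

setClassUnion("BrainAtlasOrNULL", c("BrainAtlas", "NULL"))
setClassUnion("CameraPoseOrNULL", c("CameraPose", "NULL"))

#' BrainScene: an ordered collection of actors in atlas space
#'
#' @slot atlas the reference \linkS4class{BrainAtlas} (or NULL).
#' @slot actors ordered list of \linkS4class{SceneActor}s; order is render
#'   order and is stable.
#' @slot camera current \linkS4class{CameraPose}.
#' @slot background background color, hex.
#' @exportClass BrainScene
setClass("BrainScene",
  representation(atlas = "BrainAtlasOrNULL", actors = "list",
                 camera = "CameraPose", background = "character"))

setValidity("BrainScene", function(object) {
  if (!all(vapply(object@actors, is, logical(1), class2 = "SceneActor")))
    return("actors must all be SceneActor objects")
  nm <- vapply(object@actors, function(a) a@name, character(1))
  if (anyDuplicated(nm)) return("actor names must be unique within a scene")
  TRUE
})

#' Keyframe: a time-stamped camera / style specification
#'
#' @slot time seconds, >= 0.
#' @slot camera optional \linkS4class{CameraPose} at this time.
#' @slot actorParams named list (actor name -> named list of style fields:
#'   alpha, color, visible).
#' @exportClass Keyframe
setClass("Keyframe",
  representation(time = "numeric", camera = "CameraPoseOrNULL",
                 actorParams = "list"))

setValidity("Keyframe", function(object) {
  if (length(object@time) != 1L || object@time < 0)
    return("time must be a single non-negative number")
  TRUE
})

#' SceneAnimation: keyframes over a scene
#'
#' @slot scene the \linkS4class{BrainScene} being animated.
#' @slot keyframes list of \linkS4class{Keyframe}s with strictly
#'   increasing times.
#' @slot fps frames per second, > 0.
#' @exportClass SceneAnimation
setClass("SceneAnimation",
  representation(scene = "BrainScene", keyframes = "list", fps = "numeric"))

setValidity("SceneAnimation", function(object) {
  if (length(object@fps) != 1L || object@fps <= 0)
    return("fps must be a positive scalar")
  tms <- vapply(object@keyframes, function(k) k@time, numeric(1))
  if (length(tms) > 1L && any(diff(tms) <= 0))
    return("keyframe times must be strictly increasing")
  TRUE
})

## ------- basic accessors -------

#' @rdname vertices
#' @export
setMethod("vertices", "TriMesh", function(x) x@vertices)

#' @rdname faces
#' @export
setMethod("faces", "TriMesh", function(x) x@faces)

#' @rdname vertices
#' @export
setMethod("vertices", "SceneActor", function(x) x@mesh@vertices)

#' @rdname faces
#' @export
setMethod("faces", "SceneActor", function(x) x@mesh@faces)

#' @rdname structures
#' @export
setMethod("structures", "BrainAtlas", function(x) x@structures)

#' @rdname annotation
#' @export
setMethod("annotation", "BrainAtlas", function(x) x@annotation)

#' @rdname resolutionUm
#' @export
setMethod("resolutionUm", "BrainAtlas", function(x) x@resolution)

#' @rdname resolutionUm
#' @export
setMethod("resolutionUm", "VolumeGrid", function(x) x@resolution)

#' @rdname actors
#' @export
setMethod("actors", "BrainScene", function(x) x@actors)

#' @rdname nRecords
#' @export
setMethod("nRecords", "BrainPoints", function(x) nrow(x@coordinates))

#' @rdname nRecords
#' @export
setMethod("nRecords", "Streamlines", function(x) length(x@paths))

#' @rdname nRecords
#' @export
setMethod("nRecords", "NeuronMorphology", function(x) nrow(x@nodes))

## ------- show methods -------

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
  if (nrow(object@vertices)) {
    bb <- apply(object@vertices, 2, range)
    cat(sprintf("  bounds (um): [%g, %g] x [%g, %g] x [%g, %g]\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
})

setMethod("show", "BrainAtlas", function(object) {
  cat(sprintf("BrainAtlas '%s': %d structures, annotation %s @ %s um\n",
              object@name, nrow(object@structures),
              paste(dim(object@annotation), collapse = "x"),
              paste(object@resolution, collapse = "x")))
})

setMethod("show", "BrainScene", function(object) {
  cat(sprintf("BrainScene with %d actor(s)%s\n", length(object@actors),
              if (is.null(object@atlas)) ""
              else sprintf(" in atlas '%s'", object@atlas@name)))
  for (a in object@actors)
    cat(sprintf("  - %s [%s] %d faces, alpha %.2f%s\n", a@name, a@kind,
                nrow(a@mesh@faces), a@style@alpha,
                if (a@style@visible) "" else " (hidden)"))
})

setMethod("show", "NeuronMorphology", function(object) {
  cat(sprintf("NeuronMorphology: %d nodes (%d soma, %d axon, %d dendrite)\n",
              nrow(object@nodes), sum(object@nodes$type == 1L),
              sum(object@nodes$type == 2L),
              sum(object@nodes$type %in% c(3L, 4L))))
})

setMethod("show", "SceneAnimation", function(object) {
  tms <- vapply(object@keyframes, function(k) k@time, numeric(1))
  cat(sprintf("SceneAnimation: %d keyframes over [%g, %g] s at %g fps\n",
              length(tms), if (length(tms)) min(tms) else 0,
              if (length(tms)) max(tms) else 0, object@fps))
})
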