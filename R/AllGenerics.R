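#' @title Generics for braincanvas classes
#' @description Accessor and measurement generics shared across the package's
#'   S4 classes.
#' @name braincanvas-generics
#' @keywords internal
NULL

#' Mesh vertex coordinates
#'
#' @param x an object with triangle-mesh geometry.
#' @return A numeric V x 3 matrix of vertex coordinates in micrometers.
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))

#' Mesh triangle faces
#'
#' @param x an object with triangle-mesh geometry.
#' @return An integer F x 3 matrix of 1-based vertex indices.
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))

#' Enclosed volume of a closed triangle mesh
#'
#' Computed by the divergence theorem as the absolute sum of signed
#' tetrahedron volumes; only meaningful for (near-)watertight surfaces.
#'
#' @param x a mesh-bearing object.
#' @return Volume in cubic micrometers.
#' @export
setGeneric("meshVolume", function(x) standardGeneric("meshVolume"))

#' Total surface area of a triangle mesh
#'
#' @param x a mesh-bearing object.
#' @return Area in square micrometers.
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))

#' Center of mass of a mesh
#'
#' Volume-weighted centroid for closed meshes; falls back to the
#' area-weighted surface centroid when the surface is open.
#'
#' @param x a mesh-bearing object.
#' @return Numeric length-3 point in micrometers.
#' @export
setGeneric("centerOfMass", function(x) standardGeneric("centerOfMass"))

#' Structure table of an atlas
#'
#' @param x a \linkS4class{BrainAtlas}.
#' @return A data.frame with one row per structure.
#' @export
setGeneric("structures", function(x) standardGeneric("structures"))

#' Annotation label volume of an atlas
#'
#' @param x a \linkS4class{BrainAtlas}.
#' @return A 3D integer array; voxel value is the structure id, 0 outside.
#' @export
setGeneric("annotation", function(x) standardGeneric("annotation"))

#' Voxel resolution in micrometers
#'
#' @param x an atlas or volume object.
#' @return Numeric length-3 voxel edge lengths (AP, DV, LR), micrometers.
#' @export
setGeneric("resolutionUm", function(x) standardGeneric("resolutionUm"))

#' Actors of a scene
#'
#' @param x a \linkS4class{BrainScene}.
#' @return List of \linkS4class{SceneActor} objects in render order.
#' @export
setGeneric("actors", function(x) standardGeneric("actors"))

#' Number of points / paths / nodes in a data object
#'
#' @param x a data object.
#' @return Integer count.
#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))
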