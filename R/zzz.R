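#' braincanvas: scene-based 3D visualization of anatomically registered data
#'
#' Load brain atlas bundles and standard neuroanatomy data formats,
#' query the structure hierarchy and annotation volume, convert label
#' volumes and data into triangle meshes, compose styled actors into
#' scenes, render deterministic off-screen screenshots, export
#' self-contained HTML documents and keyframe-animated frame sequences.
#'
#' @docType package
#' @name braincanvas-package
#' @aliases braincanvas
#' @import methods
#' @importFrom grDevices col2rgb rgb colors
#' @importFrom stats runif rnorm
#' @importFrom utils head read.table write.csv
#' @importFrom tools file_ext file_path_sans_ext
#' @keywords internal
NULL
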