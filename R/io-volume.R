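#' Read a volumetric TIFF stack
#'
#' Pages are slices along the first (AP) axis; each page holds a DV x LR
#' matrix, so the result has dims (AP, DV, LR). Integer TIFFs are read
#' as-is (no 0-1 rescaling), which preserves label and count volumes
#' exactly. The voxel resolution comes from the \code{resolution} argument
#' or, when omitted, from a JSON sidecar \code{<path>.json} with keys
#' \code{resolution} (and optionally \code{origin}).
#'
#' @param path path to a multi-page .tiff stack.
#' @param resolution voxel size in micrometers, scalar or length 3;
#'   overrides the sidecar.
#' @return A \linkS4class{VolumeGrid}.
#' @seealso [writeVolumeTIFF()]
#' @export
readVolumeTIFF <- function(path, resolution = NULL) {
  if (!file.exists(path)) stop(sprintf("TIFF file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop(sprintf("TIFF format error in %s: not a 3D stack (%d page)",
                 path, length(pages)))
  if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
    stop(sprintf("TIFF format error in %s: pages must be single-channel 2D",
                 path))
  arr <- aperm(simplify2array(pages), c(3L, 1L, 2L))
  origin <- c(0, 0, 0)
  if (is.null(resolution)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::fromJSON(sidecar)
      resolution <- meta$resolution
      if (!is.null(meta$origin)) origin <- as.numeric(meta$origin)
    }
  }
  if (is.null(resolution))
    stop(sprintf("no resolution for %s: pass resolution= or provide %s.json",
                 path, path))
  volumeGrid(arr, resolution, origin)
}

#' Write a volume as a multi-page TIFF stack
#'
#' Values are written as 16-bit unsigned integers (they must lie in
#' 0..65535); integer volumes round-trip exactly. A JSON sidecar
#' \code{<path>.json} carrying resolution and origin is written alongside.
#'
#' @param volume a \linkS4class{VolumeGrid} or 3D array.
#' @param path output .tiff path.
#' @param resolution voxel size when \code{volume} is a bare array.
#' @return The path, invisibly.
#' @export
writeVolumeTIFF <- function(volume, path, resolution = c(1, 1, 1)) {
  if (is(volume, "VolumeGrid")) {
    arr <- volume@values
    resolution <- volume@resolution
    origin <- volume@origin
  } else {
    arr <- volume
    origin <- c(0, 0, 0)
  }
  if (length(dim(arr)) != 3L) stop("volume must be a 3D array")
  if (any(arr < 0 | arr > 65535))
    stop("TIFF write expects values in 0..65535")
  pages <- lapply(seq_len(dim(arr)[1]),
                  function(i) arr[i, , ] / 65535)
  ok <- tryCatch({
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    TRUE
  }, error = function(e) FALSE, warning = function(w) TRUE)
  if (!ok) stop(sprintf("cannot write TIFF file: %s", path))
  jsonlite::write_json(list(resolution = resolution, origin = origin),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}
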