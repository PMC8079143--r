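#' Read tractography streamlines from JSON
#'
#' The expected dialect is a top-level object with key \code{"lines"}:
#' each line is an array of \code{{"x":..,"y":..,"z":..}} micrometer
#' points. An optional parallel \code{"intensity"} array supplies one
#' scalar per path and is ignored when absent. Paths with fewer than two
#' points are dropped with a message; the count is kept on the object.
#'
#' @param path path to a streamlines .json file.
#' @return A \linkS4class{Streamlines}.
#' @export
readStreamlines <- function(path) {
  if (!file.exists(path)) stop(sprintf("streamlines file not found: %s", path))
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$lines))
    stop(sprintf("streamlines format error in %s: missing 'lines' key", path))
  paths <- lapply(doc$lines, function(line) {
    pts <- vapply(line, function(p) c(as.numeric(p$x), as.numeric(p$y),
                                      as.numeric(p$z)), numeric(3))
    if (length(pts) == 0) matrix(numeric(0), 0, 3) else t(pts)
  })
  keep <- vapply(paths, nrow, integer(1)) >= 2L
  dropped <- sum(!keep)
  if (dropped > 0)
    message(sprintf("readStreamlines: dropped %d path(s) with < 2 points",
                    dropped))
  intensity <- numeric(0)
  if (!is.null(doc$intensity)) {
    intensity <- as.numeric(unlist(doc$intensity))
    if (length(intensity) == length(paths)) intensity <- intensity[keep]
    else intensity <- numeric(0)
  }
  new("Streamlines", paths = paths[keep], intensity = intensity,
      nDropped = as.integer(dropped))
}

#' Write streamlines to JSON
#'
#' Inverse of [readStreamlines()]; emits the same \code{"lines"} dialect.
#'
#' @param s a \linkS4class{Streamlines}.
#' @param path output .json path.
#' @return The path, invisibly.
#' @export
writeStreamlines <- function(s, path) {
  stopifnot(is(s, "Streamlines"))
  lines <- lapply(s@paths, function(p)
    lapply(seq_len(nrow(p)), function(i)
      list(x = p[i, 1], y = p[i, 2], z = p[i, 3])))
  doc <- list(lines = lines)
  if (length(s@intensity)) doc$intensity <- s@intensity
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
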