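#' Read an SWC neuron morphology file
#'
#' Parses the standard 7-column whitespace-delimited SWC format
#' (sample_id, type, x, y, z, radius, parent_id); lines starting with '#'
#' are comments. Coordinates and radii are in micrometers. Type codes
#' follow the SWC convention (1 soma, 2 axon, 3 basal dendrite, 4 apical
#' dendrite); larger codes are accepted and rendered with a default style.
#'
#' @param path path to a .swc file.
#' @return A \linkS4class{NeuronMorphology}.
#' @seealso [writeSWC()], [neuronToMeshes()]
#' @export
readSWC <- function(path) {
  if (!file.exists(path)) stop(sprintf("SWC file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    stop(sprintf("SWC format error in %s: no data lines (empty morphology)",
                 path))
  fields <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(fields)
  if (any(ncols != 7L))
    stop(sprintf("SWC format error in %s at line %d: expected 7 columns, got %d",
                 path, lineno[which(ncols != 7L)[1]], ncols[ncols != 7L][1]))
  m <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop(sprintf("SWC format error in %s at line %d: non-numeric field",
                 path, lineno[bad]))
  }
  nodes <- data.frame(sample_id = as.integer(m[, 1]),
                      type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6],
                      parent_id = as.integer(m[, 7]))
  ## tree check with line numbers before handing to the class validator
  for (i in seq_len(nrow(nodes))) {
    p <- nodes$parent_id[i]
    if (p != -1L && !(p %in% nodes$sample_id[seq_len(i - 1L)]))
      stop(sprintf(
        "SWC format error in %s at line %d: parent %d not defined earlier",
        path, lineno[i], p))
  }
  new("NeuronMorphology", nodes = nodes)
}

#' Write a NeuronMorphology to an SWC file
#'
#' Emits standard 7-column SWC preserving node order;
#' \code{readSWC(writeSWC(m))} reproduces \code{m} exactly.
#'
#' @param morph a \linkS4class{NeuronMorphology}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeSWC <- function(morph, path) {
  stopifnot(is(morph, "NeuronMorphology"))
  nd <- morph@nodes
  lines <- c("# SWC exported by braincanvas",
             sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                     nd$sample_id, nd$type, nd$x, nd$y, nd$z, nd$radius,
                     nd$parent_id))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write SWC file: %s", path))
  invisible(path)
}

#' Number of branch points of a morphology
#'
#' A branch point is a node with more than one child (the soma root is
#' counted only if it has more than one child beyond the first neurite).
#'
#' @param morph a \linkS4class{NeuronMorphology}.
#' @return Integer count of nodes with out-degree > 1.
#' @export
branchPoints <- function(morph) {
  nd <- morph@nodes
  kids <- table(nd$parent_id[nd$parent_id != -1L])
  sum(kids > 1L)
}
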