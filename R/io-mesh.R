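#' Read a surface mesh from an OBJ or STL file
#'
#' Wavefront OBJ (v/f records, 1-based indices; texture/normal components
#' in face records are ignored) and STL (binary or ASCII, auto-detected)
#' are supported. STL stores three vertices per facet; exactly coincident
#' vertices are merged on read so indexed meshes round-trip.
#'
#' @param path path to a .obj or .stl file.
#' @return A \linkS4class{TriMesh} (micrometer coordinates).
#' @seealso [writeMeshFile()]
#' @export
readMeshFile <- function(path) {
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = .readOBJ(path),
         stl = .readSTL(path),
         stop(sprintf("unsupported mesh format '.%s' (expected .obj or .stl)",
                      ext)))
}

#' Write a surface mesh to an OBJ or STL file
#'
#' The format is chosen from the file extension. OBJ keeps the indexed
#' representation; STL expands to per-facet vertices (binary little-endian
#' by default).
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param path output path ending in .obj or .stl.
#' @param ascii for STL, write the ASCII dialect instead of binary.
#' @return The path, invisibly.
#' @export
writeMeshFile <- function(mesh, path, ascii = FALSE) {
  stopifnot(is(mesh, "TriMesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = .writeOBJ(mesh, path),
         stl = .writeSTL(mesh, path, ascii = ascii),
         stop(sprintf("unsupported mesh format '.%s' (expected .obj or .stl)",
                      ext)))
  invisible(path)
}

.readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[grepl("^v\\s", lines)]
  flines <- lines[grepl("^f\\s", lines)]
  vparts <- strsplit(trimws(sub("^v\\s+", "", vlines)), "\\s+")
  verts <- suppressWarnings(
    t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3))))
  if (length(vlines) && anyNA(verts))
    stop(sprintf("OBJ format error in %s: non-numeric vertex", path))
  fparts <- strsplit(trimws(sub("^f\\s+", "", flines)), "\\s+")
  faceIdx <- lapply(fparts, function(p) {
    ## "3", "3/1" and "3/1/2" all reference vertex 3
    idx <- suppressWarnings(as.integer(sub("/.*$", "", p)))
    if (anyNA(idx) || any(idx < 1L))
      stop(sprintf("OBJ format error in %s: malformed face index", path))
    idx
  })
  ## fan-triangulate polygons with > 3 vertices
  tris <- do.call(rbind, lapply(faceIdx, function(idx) {
    if (length(idx) < 3L)
      stop(sprintf("OBJ format error in %s: face with < 3 vertices", path))
    cbind(idx[1], idx[2:(length(idx) - 1L)], idx[3:length(idx)])
  }))
  if (is.null(tris)) tris <- matrix(integer(0), 0, 3)
  if (length(tris) && max(tris) > nrow(verts))
    stop(sprintf("OBJ format error in %s: face index out of range", path))
  if (!length(vlines)) verts <- matrix(numeric(0), 0, 3)
  triMesh(verts, tris)
}

.writeOBJ <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  lines <- c("# OBJ exported by braincanvas",
             sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
             sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write OBJ file: %s", path))
}

.readSTL <- function(path) {
  size <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 80L)
  nTri <- if (size >= 84) readBin(con, "integer", 1L, size = 4L,
                                  endian = "little") else -1L
  if (nTri >= 0 && size == 84 + 50 * as.numeric(nTri)) {
    ## binary STL: 50 bytes per facet = 12 floats + uint16 attribute
    raw <- readBin(con, "raw", 50L * nTri)
    fm <- matrix(raw, nrow = 50L)
    floats <- readBin(as.vector(fm[1:48, , drop = FALSE]), "numeric",
                      n = 12L * nTri, size = 4L, endian = "little")
    fl <- matrix(floats, nrow = 12L)  # nx ny nz v1 v2 v3 per column
    tri <- t(fl[4:12, , drop = FALSE])
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (!length(vl) || length(vl) %% 3L != 0L)
      stop(sprintf("STL format error in %s: vertex count not a multiple of 3",
                   path))
    nums <- suppressWarnings(vapply(
      strsplit(trimws(sub("^\\s*vertex\\s+", "", vl)), "\\s+"),
      function(p) as.numeric(p[1:3]), numeric(3)))
    if (anyNA(nums))
      stop(sprintf("STL format error in %s: non-numeric vertex", path))
    ## nums is 3 x (3*nTri) column-per-vertex; 9 consecutive values per facet
    tri <- matrix(as.vector(nums), ncol = 9L, byrow = TRUE)
  }
  nT <- nrow(tri)
  allv <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                tri[, 7:9, drop = FALSE])
  ## merge exactly-coincident vertices to restore the indexed mesh
  key <- paste(allv[, 1], allv[, 2], allv[, 3])
  uid <- match(key, unique(key))
  verts <- allv[!duplicated(uid), , drop = FALSE]
  faces <- cbind(uid[seq_len(nT)], uid[nT + seq_len(nT)],
                 uid[2L * nT + seq_len(nT)])
  keep <- faces[, 1] != faces[, 2] & faces[, 1] != faces[, 3] &
    faces[, 2] != faces[, 3]
  triMesh(verts, faces[keep, , drop = FALSE])
}

.writeSTL <- function(mesh, path, ascii = FALSE) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  d <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- d - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  if (ascii) {
    lines <- c("solid braincanvas")
    if (nrow(f)) {
      body <- sprintf(paste0(
        "facet normal %.9g %.9g %.9g\n outer loop\n",
        "  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n",
        "  vertex %.9g %.9g %.9g\n endloop\nendfacet"),
        n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
        b[, 1], b[, 2], b[, 3], d[, 1], d[, 2], d[, 3])
      lines <- c(lines, body)
    }
    lines <- c(lines, "endsolid braincanvas")
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop(sprintf("cannot write STL file: %s", path))
  } else {
    con <- tryCatch(file(path, "wb"), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(con)) stop(sprintf("cannot write STL file: %s", path))
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    if (nrow(f)) {
      dat <- cbind(n, a, b, d)  # 12 float32 per facet
      for (i in seq_len(nrow(f))) {
        writeBin(as.numeric(dat[i, ]), con, size = 4L, endian = "little")
        writeBin(as.integer(0L), con, size = 2L, endian = "little")
      }
    }
  }
}
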