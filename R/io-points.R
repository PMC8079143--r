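#' Read point coordinates from an NPY or CSV file
#'
#' Accepts a NumPy .npy array of shape N x 3 (float32/float64/int32/int64,
#' C or Fortran order) or a delimited text file with three coordinate
#' columns. The CSV delimiter is auto-detected among comma/tab and a
#' header row is detected by a non-numeric first row. Rows containing
#' non-finite values are dropped; the count is recorded in the result and
#' reported via a message.
#'
#' @param path path to a .npy or .csv/.tsv/.txt file.
#' @return A \linkS4class{BrainPoints}; \code{x@nDropped} holds the number
#'   of discarded rows.
#' @seealso [writePointsNPY()]
#' @export
readPoints <- function(path) {
  if (!file.exists(path)) stop(sprintf("points file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  coords <- if (ext == "npy") .readNPY(path) else .readPointsCSV(path)
  if (ncol(coords) != 3L)
    stop(sprintf("points format error in %s: expected 3 columns, got %d",
                 path, ncol(coords)))
  finite <- rowSums(is.finite(coords)) == 3L
  dropped <- sum(!finite)
  if (dropped > 0)
    message(sprintf("readPoints: dropped %d row(s) with non-finite values",
                    dropped))
  out <- brainPoints(coords[finite, , drop = FALSE])
  out@nDropped <- as.integer(dropped)
  out
}

#' Write an N x 3 coordinate array as NPY
#'
#' Emits a little-endian float64 C-order NumPy v1.0 file.
#'
#' @param points a \linkS4class{BrainPoints} or numeric N x 3 matrix.
#' @param path output .npy path.
#' @return The path, invisibly.
#' @export
writePointsNPY <- function(points, path) {
  coords <- if (is(points, "BrainPoints")) points@coordinates
            else as.matrix(points)
  .writeNPY(coords, path)
  invisible(path)
}

.readPointsCSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("points file is empty: %s", path))
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  hasHeader <- anyNA(suppressWarnings(as.numeric(first)))
  dat <- utils::read.table(text = lines, sep = sep, header = hasHeader,
                           strip.white = TRUE)
  numcols <- which(vapply(dat, is.numeric, logical(1)))
  if (length(numcols) < 3L && ncol(dat) != 3L)
    stop(sprintf("points format error in %s: expected 3 coordinate columns, got %d",
                 path, ncol(dat)))
  if (ncol(dat) != 3L) dat <- dat[, numcols[1:3], drop = FALSE]
  m <- as.matrix(dat)
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

## Minimal NumPy .npy (format version 1.0) reader for 2D numeric arrays.
.readNPY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop(sprintf("not an NPY file: %s", path))
  ver <- readBin(con, "raw", 2L)
  hlen <- if (as.integer(ver[1]) >= 2L)
    readBin(con, "integer", 1L, size = 4L, endian = "little")
  else readBin(con, "integer", 1L, size = 2L, signed = FALSE,
               endian = "little")
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  shape <- as.integer(strsplit(gsub("\\s", "", shapeStr), ",")[[1]])
  shape <- shape[!is.na(shape)]
  n <- prod(shape)
  endian <- if (substr(descr, 1, 1) == ">") "big" else "little"
  code <- sub("^[<>|=]", "", descr)
  vals <- switch(code,
    f8 = readBin(con, "numeric", n, size = 8L, endian = endian),
    f4 = readBin(con, "numeric", n, size = 4L, endian = endian),
    i8 = readBin(con, "numeric", n, size = 8L, endian = endian),
    i4 = as.numeric(readBin(con, "integer", n, size = 4L, endian = endian)),
    i2 = as.numeric(readBin(con, "integer", n, size = 2L, endian = endian)),
    u2 = as.numeric(readBin(con, "integer", n, size = 2L, signed = FALSE,
                            endian = endian)),
    stop(sprintf("unsupported NPY dtype '%s' in %s", descr, path)))
  if (length(vals) != n)
    stop(sprintf("NPY file truncated: %s", path))
  if (length(shape) == 1L) shape <- c(shape, 1L)
  if (length(shape) != 2L)
    stop(sprintf("points format error in %s: expected a 2D array", path))
  m <- if (fortran) matrix(vals, nrow = shape[1], ncol = shape[2])
       else matrix(vals, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  m
}

.writeNPY <- function(m, path) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  ## pad so that magic(6) + ver(2) + hlen(2) + header is a multiple of 64
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- tryCatch(file(path, "wb"), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) stop(sprintf("cannot write NPY file: %s", path))
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(t(m)), con, size = 8L, endian = "little")
}
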