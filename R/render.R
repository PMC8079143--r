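## Deterministic off-screen rendering.
##
## A software rasterizer: orthographic projection through the scene
## camera, per-face Lambert shading, triangles depth-sorted and painted
## back to front with alpha blending. Entirely CPU-side, so repeated
## renders of the same scene and camera are pixel-identical.

.cameraBasis <- function(camera) {
  dir <- .normalize(camera@focalPoint - camera@position)
  right <- .cross(dir, camera@viewup)
  if (sqrt(sum(right^2)) < 1e-9)
    stop("camera viewup is parallel to the viewing direction")
  right <- .normalize(right)
  up <- .cross(right, dir)
  list(dir = dir, right = right, up = up)
}

#' Render a scene to a PNG screenshot
#'
#' Off-screen software rendering: the image always has exactly the
#' requested pixel dimensions and no window or display is required.
#'
#' @param scene a \linkS4class{BrainScene}.
#' @param path output .png path.
#' @param width,height image size in pixels.
#' @param camera \linkS4class{CameraPose} override (default: the
#'   scene's camera).
#' @return The path, invisibly.
#' @export
renderScreenshot <- function(scene, path, width = 800L, height = 600L,
                             camera = NULL) {
  img <- .rasterizeScene(scene, width, height, camera)
  ok <- tryCatch({ png::writePNG(img, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write PNG file: %s", path))
  invisible(path)
}

## returns a height x width x 3 array in [0, 1]
.rasterizeScene <- function(scene, width, height, camera = NULL) {
  width <- as.integer(width); height <- as.integer(height)
  if (width < 1L || height < 1L) stop("width and height must be positive")
  cam <- if (is.null(camera)) scene@camera else camera
  bg <- .colorToUnit(scene@background)
  R <- matrix(bg[1], height, width)
  G <- matrix(bg[2], height, width)
  B <- matrix(bg[3], height, width)
  vis <- Filter(function(a) a@style@visible && nrow(a@mesh@faces) > 0,
                scene@actors)
  if (!length(vis)) return(.stackRGB(R, G, B))
  basis <- .cameraBasis(cam)
  allVerts <- do.call(rbind, lapply(vis, function(a) a@mesh@vertices))
  diag <- .bboxDiag(allVerts)
  if (!is.finite(diag) || diag == 0) diag <- 1
  s <- cam@zoom * 0.9 * min(width, height) / diag
  ## gather all faces with per-face color, alpha, depth
  px <- list(); py <- list(); dep <- list(); fcol <- list(); fal <- list()
  fidx <- list()
  off <- 0L
  for (a in vis) {
    v <- a@mesh@vertices
    rel <- sweep(v, 2, cam@focalPoint)
    x <- width / 2 + (rel %*% basis$right) * s
    y <- height / 2 - (rel %*% basis$up) * s
    z <- rel %*% basis$dir
    f <- a@mesh@faces
    e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
    n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    nl <- sqrt(rowSums(n^2)); nl[nl == 0] <- 1
    lam <- abs((n / nl) %*% basis$dir)
    base <- .colorToUnit(a@style@color)
    shade <- 0.35 + 0.65 * as.vector(lam)
    px[[length(px) + 1L]] <- cbind(x[f[, 1]], x[f[, 2]], x[f[, 3]])
    py[[length(py) + 1L]] <- cbind(y[f[, 1]], y[f[, 2]], y[f[, 3]])
    dep[[length(dep) + 1L]] <- (z[f[, 1]] + z[f[, 2]] + z[f[, 3]]) / 3
    fcol[[length(fcol) + 1L]] <- outer(shade, base)
    fal[[length(fal) + 1L]] <- rep(a@style@alpha, nrow(f))
  }
  px <- do.call(rbind, px); py <- do.call(rbind, py)
  dep <- unlist(dep); fal <- unlist(fal)
  fcol <- do.call(rbind, fcol)
  ord <- order(dep, decreasing = TRUE)  # far first (painter)
  for (fi in ord) {
    x1 <- px[fi, 1]; x2 <- px[fi, 2]; x3 <- px[fi, 3]
    y1 <- py[fi, 1]; y2 <- py[fi, 2]; y3 <- py[fi, 3]
    xmin <- max(1L, floor(min(x1, x2, x3)))
    xmax <- min(width, ceiling(max(x1, x2, x3)))
    ymin <- max(1L, floor(min(y1, y2, y3)))
    ymax <- min(height, ceiling(max(y1, y2, y3)))
    if (xmin > xmax || ymin > ymax) next
    xs <- xmin:xmax; ys <- ymin:ymax
    nx <- length(xs); ny <- length(ys)
    X <- matrix(xs, ny, nx, byrow = TRUE)
    Y <- matrix(ys, ny, nx)
    w0 <- (x2 - x1) * (Y - y1) - (y2 - y1) * (X - x1)
    w1 <- (x3 - x2) * (Y - y2) - (y3 - y2) * (X - x2)
    w2 <- (x1 - x3) * (Y - y3) - (y1 - y3) * (X - x3)
    inside <- (w0 >= 0 & w1 >= 0 & w2 >= 0) |
              (w0 <= 0 & w1 <= 0 & w2 <= 0)
    if (!any(inside)) next
    al <- fal[fi]
    idx <- which(inside)
    rows <- ((idx - 1L) %% ny) + ymin
    cols <- ((idx - 1L) %/% ny) + xmin
    lin <- rows + (cols - 1L) * height
    R[lin] <- (1 - al) * R[lin] + al * fcol[fi, 1]
    G[lin] <- (1 - al) * G[lin] + al * fcol[fi, 2]
    B[lin] <- (1 - al) * B[lin] + al * fcol[fi, 3]
  }
  .stackRGB(R, G, B)
}

.stackRGB <- function(R, G, B) {
  out <- array(0, c(nrow(R), ncol(R), 3L))
  out[, , 1] <- R; out[, , 2] <- G; out[, , 3] <- B
  out
}
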