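## Mesh interrogation and construction: volumes, centroids, slicing,
## sphere glyphs, neurite tubes, containment and intersection tests.

#' @rdname meshVolume
#' @export
setMethod("meshVolume", "TriMesh", function(x) abs(.signedVolume(x)))

#' @rdname meshVolume
#' @export
setMethod("meshVolume", "SceneActor", function(x) abs(.signedVolume(x@mesh)))

.faceGeometry <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  d <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- d - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  list(a = a, b = b, d = d, normal2 = n, area = sqrt(rowSums(n^2)) / 2)
}

#' @rdname surfaceArea
#' @export
setMethod("surfaceArea", "TriMesh", function(x) {
  if (!nrow(x@faces)) return(0)
  sum(.faceGeometry(x)$area)
})

## TRUE when every edge is shared by exactly two faces
.isClosed <- function(mesh) {
  f <- mesh@faces
  if (!nrow(f)) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' @rdname centerOfMass
#' @export
setMethod("centerOfMass", "TriMesh", function(x) {
  if (isEmptyMesh(x)) stop("empty mesh: center of mass is undefined")
  g <- .faceGeometry(x)
  vol <- .signedVolume(x)
  ## volume centroid when the surface is closed enough for the signed
  ## volume to be trustworthy; area centroid otherwise
  if (.isClosed(x) && abs(vol) > 0) {
    vi <- (g$a[, 1] * (g$b[, 2] * g$d[, 3] - g$b[, 3] * g$d[, 2]) +
           g$a[, 2] * (g$b[, 3] * g$d[, 1] - g$b[, 1] * g$d[, 3]) +
           g$a[, 3] * (g$b[, 1] * g$d[, 2] - g$b[, 2] * g$d[, 1])) / 6
    cen <- (g$a + g$b + g$d) / 4
    colSums(cen * vi) / sum(vi)
  } else {
    cen <- (g$a + g$b + g$d) / 3
    colSums(cen * g$area) / sum(g$area)
  }
})

#' @rdname centerOfMass
#' @export
setMethod("centerOfMass", "SceneActor", function(x) centerOfMass(x@mesh))

#' Euclidean distance between the centers of two meshes
#'
#' @param a,b \linkS4class{TriMesh} (or \linkS4class{SceneActor}) objects.
#' @return Distance in micrometers between the centers of mass.
#' @export
distanceBetween <- function(a, b) {
  if (is(a, "SceneActor")) a <- a@mesh
  if (is(b, "SceneActor")) b <- b@mesh
  sqrt(sum((centerOfMass(a) - centerOfMass(b))^2))
}

#' Slice a mesh with a plane, capping the cut
#'
#' Keeps the part of the mesh on one side of the plane. With
#' \code{keep = "below"} the points p with (p - origin) . normal <= 0 are
#' retained (the normal points into the discarded half); \code{"above"}
#' keeps the complement. The cut cross-section is closed with a fan cap
#' so that enclosed volume is conserved: volume(below) + volume(above)
#' equals the original volume. A plane that misses the mesh returns the
#' mesh unchanged (or the empty mesh when everything is discarded).
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param plane a \linkS4class{Plane}.
#' @param keep "below" (default) or "above".
#' @return The capped sub-mesh as a \linkS4class{TriMesh}.
#' @export
sliceMesh <- function(mesh, plane, keep = c("below", "above")) {
  keep <- match.arg(keep)
  stopifnot(is(mesh, "TriMesh"), is(plane, "Plane"))
  if (isEmptyMesh(mesh)) return(mesh)
  n <- plane@normal
  if (keep == "above") n <- -n
  v <- mesh@vertices
  s <- (v[, 1] - plane@origin[1]) * n[1] +
       (v[, 2] - plane@origin[2]) * n[2] +
       (v[, 3] - plane@origin[3]) * n[3]
  kept <- s <= 0
  if (all(kept)) return(mesh)
  if (!any(kept)) return(emptyMesh())
  f <- mesh@faces
  fk <- matrix(kept[f], ncol = 3L)
  nKept <- rowSums(fk)
  newVerts <- list(v)
  vOff <- nrow(v)
  outFaces <- list(f[nKept == 3L, , drop = FALSE])
  cutA <- list(); cutB <- list()
  interp <- function(i, j) {
    ## intersection point on edge i(kept) -> j(discarded)
    t <- s[i] / (s[i] - s[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  mixed <- which(nKept == 1L | nKept == 2L)
  for (fi in mixed) {
    tri <- f[fi, ]
    k <- fk[fi, ]
    ## rotate so the pattern is (K,D,D) or (K,K,D); rotation keeps winding
    rot <- if (sum(k) == 1L) which(k) else which(!k) %% 3L + 1L
    ord <- ((rot - 1L + 0:2) %% 3L) + 1L
    tri <- tri[ord]; k <- k[ord]
    if (sum(k) == 1L) {               # K D D -> triangle K, a, b
      a <- interp(tri[1], tri[2])
      b <- interp(tri[1], tri[3])
      newVerts[[length(newVerts) + 1L]] <- rbind(a, b)
      ia <- vOff + 1L; ib <- vOff + 2L; vOff <- vOff + 2L
      outFaces[[length(outFaces) + 1L]] <- rbind(c(tri[1], ia, ib))
      cutA[[length(cutA) + 1L]] <- ia
      cutB[[length(cutB) + 1L]] <- ib
    } else {                          # K K D -> quad K1 K2 a b
      a <- interp(tri[2], tri[3])
      b <- interp(tri[1], tri[3])
      newVerts[[length(newVerts) + 1L]] <- rbind(a, b)
      ia <- vOff + 1L; ib <- vOff + 2L; vOff <- vOff + 2L
      outFaces[[length(outFaces) + 1L]] <-
        rbind(c(tri[1], tri[2], ia), c(tri[1], ia, ib))
      cutA[[length(cutA) + 1L]] <- ia
      cutB[[length(cutB) + 1L]] <- ib
    }
  }
  allV <- do.call(rbind, newVerts)
  dimnames(allV) <- NULL
  ## cap: one common apex on the plane; triangles (apex, b, a) reverse the
  ## directed cut edges (a -> b) so boundaries cancel and volume is exact
  if (length(cutA)) {
    ia <- unlist(cutA); ib <- unlist(cutB)
    apex <- colMeans(allV[c(ia, ib), , drop = FALSE])
    allV <- rbind(allV, apex)
    apexIdx <- nrow(allV)
    capF <- cbind(apexIdx, ib, ia)
    capF <- capF[capF[, 2] != capF[, 3], , drop = FALSE]
    outFaces[[length(outFaces) + 1L]] <- capF
  }
  allF <- do.call(rbind, outFaces)
  ## drop vertices that are no longer referenced
  used <- sort(unique(as.vector(allF)))
  remap <- integer(nrow(allV)); remap[used] <- seq_along(used)
  triMesh(allV[used, , drop = FALSE],
          matrix(remap[allF], ncol = 3L))
}

## ------- primitive glyph meshes -------

.icoCache <- new.env(parent = emptyenv())

#' Unit icosphere mesh
#'
#' Icosahedron subdivided \code{subdivisions} times, vertices on the unit
#' sphere. Subdivision 0 has 12 vertices / 20 faces; 1 has 42 / 80.
#'
#' @param subdivisions non-negative integer.
#' @return A closed \linkS4class{TriMesh} of radius 1 centered at origin.
#' @export
icosphere <- function(subdivisions = 1L) {
  key <- as.character(subdivisions)
  if (!is.null(.icoCache[[key]])) return(.icoCache[[key]])
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (it in seq_len(subdivisions)) {
    edgeKey <- character(0); edgeIdx <- integer(0)
    midpoint <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      pos <- match(k, edgeKey)
      if (!is.na(pos)) return(edgeIdx[pos])
      m <- v[i, ] + v[j, ]
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      edgeKey <<- c(edgeKey, k)
      edgeIdx <<- c(edgeIdx, nrow(v))
      nrow(v)
    }
    nf <- matrix(integer(0), 0, 3)
    for (r in seq_len(nrow(f))) {
      i <- f[r, 1]; j <- f[r, 2]; k <- f[r, 3]
      a <- midpoint(i, j); b <- midpoint(j, k); d <- midpoint(k, i)
      nf <- rbind(nf, c(i, a, d), c(j, b, a), c(k, d, b), c(a, b, d))
    }
    f <- nf
  }
  m <- triMesh(v, f)
  if (.signedVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  .icoCache[[key]] <- m
  m
}

#' Instance a sphere glyph at every point
#'
#' One template icosphere is copied to each coordinate, so the merged
#' mesh has N x (template vertex count) vertices.
#'
#' @param points a \linkS4class{BrainPoints} or numeric N x 3 matrix.
#' @param radius sphere radius in micrometers, > 0.
#' @param subdivisions icosphere subdivision level (default 1: 42
#'   vertices per sphere).
#' @return A \linkS4class{TriMesh}; empty for an empty point set.
#' @export
pointsToSpheres <- function(points, radius, subdivisions = 1L) {
  if (radius <= 0) stop("radius must be positive")
  coords <- if (is(points, "BrainPoints")) points@coordinates
            else as.matrix(points)
  n <- nrow(coords)
  if (!n) return(emptyMesh())
  tmpl <- icosphere(subdivisions)
  tv <- tmpl@vertices * radius
  nv <- nrow(tv); nf <- nrow(tmpl@faces)
  verts <- tv[rep(seq_len(nv), n), , drop = FALSE] +
    coords[rep(seq_len(n), each = nv), , drop = FALSE]
  offs <- rep((seq_len(n) - 1L) * nv, each = nf)
  faceBlock <- tmpl@faces[rep(seq_len(nf), n), , drop = FALSE] + offs
  triMesh(verts, faceBlock)
}

#' Sweep a polyline into a tube mesh
#'
#' Parallel-transport frames along the path, a regular polygon
#' cross-section, quad side walls and fan end caps.
#'
#' @param path numeric n x 3 matrix of points (n >= 2), micrometers.
#' @param radius tube radius, > 0.
#' @param sides cross-section tessellation (default 12).
#' @return A closed \linkS4class{TriMesh}.
#' @export
tubeMesh <- function(path, radius, sides = 12L) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) stop("tube path needs at least 2 points")
  if (radius <= 0) stop("radius must be positive")
  n <- nrow(path)
  tang <- matrix(0, n, 3)
  tang[1, ] <- path[2, ] - path[1, ]
  tang[n, ] <- path[n, ] - path[n - 1, ]
  if (n > 2L)
    tang[2:(n - 1), ] <- path[3:n, , drop = FALSE] -
      path[1:(n - 2), , drop = FALSE]
  lens <- sqrt(rowSums(tang^2)); lens[lens == 0] <- 1
  tang <- tang / lens
  ## initial normal: any direction not parallel to the first tangent
  ref <- if (abs(tang[1, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  nrm <- .normalize(.cross(tang[1, ], ref))
  theta <- 2 * pi * (seq_len(sides) - 1L) / sides
  verts <- matrix(0, n * sides, 3)
  for (i in seq_len(n)) {
    if (i > 1L) {  # transport the frame: remove the new tangent component
      nrm <- nrm - sum(nrm * tang[i, ]) * tang[i, ]
      l <- sqrt(sum(nrm^2))
      nrm <- if (l < 1e-12) .normalize(.cross(tang[i, ],
        if (abs(tang[i, 1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))) else nrm / l
    }
    bin <- .cross(tang[i, ], nrm)
    ring <- path[rep(i, sides), , drop = FALSE] +
      radius * (outer(cos(theta), nrm) + outer(sin(theta), bin))
    verts[((i - 1L) * sides + 1L):(i * sides), ] <- ring
  }
  faces <- matrix(integer(0), 0, 3)
  for (i in seq_len(n - 1L)) {
    a <- (i - 1L) * sides + seq_len(sides)
    b <- i * sides + seq_len(sides)
    a2 <- c(a[-1], a[1]); b2 <- c(b[-1], b[1])
    faces <- rbind(faces, cbind(a, b, b2), cbind(a, b2, a2))
  }
  ## end caps
  verts <- rbind(verts, path[1, ], path[n, ])
  c1 <- nrow(verts) - 1L; c2 <- nrow(verts)
  r1 <- seq_len(sides); r1n <- c(r1[-1], r1[1])
  r2 <- (n - 1L) * sides + seq_len(sides); r2n <- c(r2[-1], r2[1])
  ## caps must traverse their boundary rings opposite to the wall quads
  faces <- rbind(faces, cbind(c1, r1, r1n), cbind(c2, r2n, r2))
  m <- triMesh(verts, faces)
  if (.signedVolume(m) < 0) m@faces <- m@faces[, c(1, 3, 2)]
  m
}

#' Convert a neuron morphology to part meshes
#'
#' Soma nodes become spheres (radius scaled by \code{somaRadiusScale});
#' every parent-child segment becomes a capped tube whose radius is the
#' child node's SWC radius (\code{neuriteRadiusMode = "swc"}) or a fixed
#' value (pass a number). Parts are grouped by SWC type code: "soma" (1),
#' "axon" (2), "dendrites" (3), "apical_dendrites" (4), "other" (rest).
#'
#' @param morph a \linkS4class{NeuronMorphology}.
#' @param somaRadiusScale multiplier on soma radii (default 1).
#' @param neuriteRadiusMode "swc" or a fixed radius in micrometers.
#' @param sides tube tessellation (default 8).
#' @return Named list of \linkS4class{TriMesh}, one per present part.
#' @export
neuronToMeshes <- function(morph, somaRadiusScale = 1,
                           neuriteRadiusMode = "swc", sides = 8L) {
  stopifnot(is(morph, "NeuronMorphology"))
  nd <- morph@nodes
  pos <- as.matrix(nd[, c("x", "y", "z")])
  partOf <- function(tp) switch(as.character(tp), `1` = "soma",
                                `2` = "axon", `3` = "dendrites",
                                `4` = "apical_dendrites", "other")
  parts <- list()
  soma <- which(nd$type == 1L)
  if (length(soma)) {
    spheres <- lapply(soma, function(i) {
      s <- icosphere(1L)
      triMesh(s@vertices * (nd$radius[i] * somaRadiusScale) +
                matrix(pos[i, ], nrow(s@vertices), 3, byrow = TRUE),
              s@faces)
    })
    parts$soma <- mergeMeshes(spheres)
  }
  seg <- which(nd$parent_id != -1L & nd$type != 1L)
  if (length(seg)) {
    pidx <- match(nd$parent_id[seg], nd$sample_id)
    grp <- vapply(nd$type[seg], partOf, character(1))
    for (g in unique(grp)) {
      rows <- seg[grp == g]
      prows <- pidx[grp == g]
      tubes <- lapply(seq_along(rows), function(k) {
        r <- if (identical(neuriteRadiusMode, "swc")) nd$radius[rows[k]]
             else as.numeric(neuriteRadiusMode)
        p0 <- pos[prows[k], ]; p1 <- pos[rows[k], ]
        if (all(p0 == p1)) return(emptyMesh())
        tubeMesh(rbind(p0, p1), r, sides = sides)
      })
      parts[[g]] <- mergeMeshes(tubes)
    }
  }
  parts
}

#' Sweep streamline paths into one tube mesh
#'
#' @param s a \linkS4class{Streamlines}.
#' @param radius tube radius in micrometers, > 0.
#' @param sides cross-section tessellation (default 12).
#' @return A merged \linkS4class{TriMesh}; empty for empty streamlines.
#' @export
streamlinesToMesh <- function(s, radius, sides = 12L) {
  stopifnot(is(s, "Streamlines"))
  if (radius <= 0) stop("radius must be positive")
  if (!length(s@paths)) return(emptyMesh())
  mergeMeshes(lapply(s@paths, tubeMesh, radius = radius, sides = sides))
}

## ------- containment and intersection -------

## fixed, slightly irrational ray direction avoids grazing axis-aligned
## facets of voxel-derived meshes
.RAY_DIR <- c(0.5773502691896258, 0.5345224838248488, 0.6172133998483676)

## Moeller-Trumbore: does ray p + t*dir (t > 0) hit each triangle?
.rayHits <- function(p, dir, g) {
  h <- c(dir[2] * g$e2[, 3] - dir[3] * g$e2[, 2],
         dir[3] * g$e2[, 1] - dir[1] * g$e2[, 3],
         dir[1] * g$e2[, 2] - dir[2] * g$e2[, 1])
  h <- matrix(h, ncol = 3)
  det <- rowSums(g$e1 * h)
  ok <- abs(det) > 1e-12
  sv <- cbind(p[1] - g$a[, 1], p[2] - g$a[, 2], p[3] - g$a[, 3])
  u <- rowSums(sv * h) / det
  q <- cbind(sv[, 2] * g$e1[, 3] - sv[, 3] * g$e1[, 2],
             sv[, 3] * g$e1[, 1] - sv[, 1] * g$e1[, 3],
             sv[, 1] * g$e1[, 2] - sv[, 2] * g$e1[, 1])
  vv <- (dir[1] * q[, 1] + dir[2] * q[, 2] + dir[3] * q[, 3]) / det
  t <- rowSums(g$e2 * q) / det
  ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & t > 1e-12
}

.rayGeom <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  list(a = a,
       e1 = v[f[, 2], , drop = FALSE] - a,
       e2 = v[f[, 3], , drop = FALSE] - a)
}

#' Point-in-mesh containment by ray parity
#'
#' Casts a ray from each point and counts triangle crossings; an odd
#' count means inside. Requires a closed mesh; for open meshes a warning
#' is emitted and the parity result is returned best-effort.
#'
#' @param p length-3 point or N x 3 matrix of points (micrometers).
#' @param mesh a \linkS4class{TriMesh}.
#' @return Logical vector, one value per point.
#' @export
pointInMesh <- function(p, mesh) {
  stopifnot(is(mesh, "TriMesh"))
  if (isEmptyMesh(mesh)) stop("empty mesh: containment is undefined")
  if (!.isClosed(mesh))
    warning("mesh is not closed; containment result is best-effort")
  pts <- if (is.matrix(p)) p else matrix(p, 1, 3)
  g <- .rayGeom(mesh)
  bb <- .bbox(mesh@vertices)
  out <- logical(nrow(pts))
  inBox <- pts[, 1] >= bb[1, 1] & pts[, 1] <= bb[2, 1] &
    pts[, 2] >= bb[1, 2] & pts[, 2] <= bb[2, 2] &
    pts[, 3] >= bb[1, 3] & pts[, 3] <= bb[2, 3]
  for (i in which(inBox))
    out[i] <- sum(.rayHits(pts[i, ], .RAY_DIR, g)) %% 2L == 1L
  out
}

## segment pq vs triangles: any intersection?
.segmentHitsAny <- function(p, q, g) {
  dir <- q - p
  len <- sqrt(sum(dir^2))
  if (len == 0) return(FALSE)
  h <- matrix(c(dir[2] * g$e2[, 3] - dir[3] * g$e2[, 2],
                dir[3] * g$e2[, 1] - dir[1] * g$e2[, 3],
                dir[1] * g$e2[, 2] - dir[2] * g$e2[, 1]), ncol = 3)
  det <- rowSums(g$e1 * h)
  ok <- abs(det) > 1e-12
  sv <- cbind(p[1] - g$a[, 1], p[2] - g$a[, 2], p[3] - g$a[, 3])
  u <- rowSums(sv * h) / det
  q2 <- cbind(sv[, 2] * g$e1[, 3] - sv[, 3] * g$e1[, 2],
              sv[, 3] * g$e1[, 1] - sv[, 1] * g$e1[, 3],
              sv[, 1] * g$e1[, 2] - sv[, 2] * g$e1[, 1])
  vv <- (dir[1] * q2[, 1] + dir[2] * q2[, 2] + dir[3] * q2[, 3]) / det
  t <- rowSums(g$e2 * q2) / det
  any(ok & u >= 0 & vv >= 0 & (u + vv) <= 1 & t >= 0 & t <= 1)
}

#' Do two meshes intersect?
#'
#' Broad-phase bounding-box rejection, then vertex containment (either
#' way), then edge-vs-surface crossing tests restricted to the box
#' overlap region.
#'
#' @param a,b closed \linkS4class{TriMesh} objects.
#' @return TRUE when the surfaces touch or one mesh lies inside the other.
#' @export
meshesIntersect <- function(a, b) {
  if (is(a, "SceneActor")) a <- a@mesh
  if (is(b, "SceneActor")) b <- b@mesh
  if (isEmptyMesh(a) || isEmptyMesh(b)) return(FALSE)
  ba <- .bbox(a@vertices); bb <- .bbox(b@vertices)
  if (any(ba[1, ] > bb[2, ] | bb[1, ] > ba[2, ])) return(FALSE)
  if (any(suppressWarnings(pointInMesh(a@vertices, b)))) return(TRUE)
  if (any(suppressWarnings(pointInMesh(b@vertices, a)))) return(TRUE)
  ## edges of a crossing the surface of b, limited to the overlap box
  lo <- pmax(ba[1, ], bb[1, ]); hi <- pmin(ba[2, ], bb[2, ])
  inBox <- function(v) v[, 1] >= lo[1] & v[, 1] <= hi[1] &
    v[, 2] >= lo[2] & v[, 2] <= hi[2] & v[, 3] >= lo[3] & v[, 3] <= hi[3]
  fa <- a@faces
  e <- unique(rbind(fa[, c(1, 2)], fa[, c(2, 3)], fa[, c(3, 1)]))
  eKeep <- inBox(a@vertices[e[, 1], , drop = FALSE]) |
    inBox(a@vertices[e[, 2], , drop = FALSE])
  e <- e[eKeep, , drop = FALSE]
  g <- .rayGeom(b)
  for (i in seq_len(nrow(e)))
    if (.segmentHitsAny(a@vertices[e[i, 1], ], a@vertices[e[i, 2], ], g))
      return(TRUE)
  FALSE
}
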