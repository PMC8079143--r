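## The Scene: actor composition, region resolution, slicing, cameras,
## HTML export.

#' Create a scene in an atlas space
#'
#' The scene starts with the atlas root-region actor (rendered light gray
#' and mostly transparent, as an anatomical reference) unless
#' \code{addRoot = FALSE}, and a default "frontal" camera framing the
#' root bounding box.
#'
#' @param atlas a \linkS4class{BrainAtlas}, or NULL for a free-standing
#'   scene.
#' @param addRoot add the root-region actor (default TRUE; ignored
#'   without an atlas).
#' @param background background color (default white).
#' @return A \linkS4class{BrainScene}.
#' @examples \dontrun{
#' scene <- brainScene(atlas)
#' scene <- addBrainRegion(scene, c("VISp", "MOs"), alpha = 0.5)
#' }
#' @export
brainScene <- function(atlas = NULL, addRoot = TRUE, background = "white") {
  acts <- list()
  if (!is.null(atlas) && addRoot) {
    m <- regionMesh(atlas, atlas@rootAcronym)
    acts <- list(new("SceneActor", name = atlas@rootAcronym, kind = "region",
                     mesh = m,
                     style = actorStyle(color = "#d3d3d3", alpha = 0.1),
                     source = atlas@rootAcronym))
  }
  cam <- if (!is.null(atlas))
    .presetFromBox(.rootBox(atlas), "frontal")
  else cameraPose(c(-1, 0, 0), c(0, 0, 0))
  new("BrainScene", atlas = atlas, actors = acts, camera = cam,
      background = normalizeColor(background))
}

.rootBox <- function(atlas) {
  m <- regionMesh(atlas, atlas@rootAcronym)
  .bbox(m@vertices)
}

.presetFromBox <- function(bb, name) {
  center <- colMeans(bb)
  diag <- sqrt(sum((bb[2, ] - bb[1, ])^2))
  d <- max(diag, 1) * 1.5
  switch(name,
    frontal  = cameraPose(center - c(d, 0, 0), center, c(0, -1, 0)),
    sagittal = cameraPose(center - c(0, 0, d), center, c(0, -1, 0)),
    top      = cameraPose(center - c(0, d, 0), center, c(-1, 0, 0)),
    stop(sprintf("unknown camera preset '%s' (frontal, sagittal, top)",
                 name)))
}

#' Named camera presets computed from the scene's root bounding box
#'
#' @param scene a \linkS4class{BrainScene}.
#' @param name "frontal", "sagittal" or "top".
#' @return A \linkS4class{CameraPose}.
#' @export
cameraPreset <- function(scene, name = "frontal") {
  bb <- if (!is.null(scene@atlas)) .rootBox(scene@atlas)
        else .sceneBox(scene)
  .presetFromBox(bb, name)
}

.sceneBox <- function(scene) {
  vs <- lapply(Filter(function(a) a@style@visible && nrow(a@mesh@vertices),
                      scene@actors), function(a) a@mesh@vertices)
  if (!length(vs)) return(rbind(c(0, 0, 0), c(1, 1, 1)))
  .bbox(do.call(rbind, vs))
}

## unique actor names: append _2, _3, ... on collision
.uniqueName <- function(name, existing) {
  if (!name %in% existing) return(name)
  i <- 2L
  while (paste(name, i, sep = "_") %in% existing) i <- i + 1L
  paste(name, i, sep = "_")
}

#' Add actors to a scene
#'
#' Actor names are made unique by suffixing "_2", "_3", ... when needed;
#' render order is the order of addition and is stable.
#'
#' @param scene a \linkS4class{BrainScene}.
#' @param actor a \linkS4class{SceneActor} or list of them.
#' @return The updated scene.
#' @export
addActor <- function(scene, actor) {
  if (is(actor, "SceneActor")) actor <- list(actor)
  for (a in actor) {
    a@name <- .uniqueName(a@name,
                          vapply(scene@actors, function(x) x@name,
                                 character(1)))
    scene@actors[[length(scene@actors) + 1L]] <- a
  }
  validObject(scene)
  scene
}

#' Add brain-region actors to a scene
#'
#' All acronyms are validated before anything is added, so an unknown
#' acronym leaves the scene unchanged. Region color defaults to the
#' structure's atlas rgb.
#'
#' @param scene a \linkS4class{BrainScene} with an atlas.
#' @param acronyms character vector of region acronyms.
#' @param alpha region opacity (default 0.3).
#' @param color override color applied to all listed regions, or NULL
#'   for the per-structure atlas colors.
#' @return The updated scene.
#' @export
addBrainRegion <- function(scene, acronyms, alpha = 0.3, color = NULL) {
  if (is.null(scene@atlas)) stop("scene has no atlas")
  rows <- lapply(acronyms, function(a) .structureRow(scene@atlas, a))
  meshes <- lapply(acronyms, function(a) regionMesh(scene@atlas, a))
  for (i in seq_along(acronyms)) {
    col <- if (is.null(color))
      c(rows[[i]]$r, rows[[i]]$g, rows[[i]]$b) else color
    actor <- new("SceneActor", name = rows[[i]]$acronym, kind = "region",
                 mesh = meshes[[i]],
                 style = actorStyle(color = col, alpha = alpha),
                 source = rows[[i]]$acronym)
    scene <- addActor(scene, actor)
  }
  scene
}

#' Slice scene actors with a plane
#'
#' Replaces each targeted actor's mesh with its capped slice; untargeted
#' actors are untouched. Actors that fall entirely on the discarded side
#' end up with an empty mesh and are marked invisible.
#'
#' @param scene a \linkS4class{BrainScene}.
#' @param plane a \linkS4class{Plane}.
#' @param actorNames names of the actors to slice (default: all).
#' @param keep "below" (default) or "above"; see [sliceMesh()].
#' @return The updated scene.
#' @export
sceneSlice <- function(scene, plane, actorNames = NULL,
                       keep = c("below", "above")) {
  keep <- match.arg(keep)
  nms <- vapply(scene@actors, function(a) a@name, character(1))
  if (is.null(actorNames)) actorNames <- nms
  unknown <- setdiff(actorNames, nms)
  if (length(unknown))
    .unknownKeyStop(unknown[1], nms, "actor")
  for (i in seq_along(scene@actors)) {
    if (!nms[i] %in% actorNames) next
    sliced <- sliceMesh(scene@actors[[i]]@mesh, plane, keep = keep)
    scene@actors[[i]]@mesh <- sliced
    if (isEmptyMesh(sliced)) scene@actors[[i]]@style@visible <- FALSE
  }
  scene
}

#' Export a scene as a single self-contained HTML document
#'
#' Every visible actor's geometry (vertices, faces) and style is embedded
#' in one JSON block inside the file; a small inline canvas viewer renders
#' a rotating orthographic preview without any external assets. The
#' number of embedded geometries equals the number of visible actors.
#'
#' @param scene a \linkS4class{BrainScene}.
#' @param path output .html path.
#' @return The path, invisibly.
#' @export
exportHTML <- function(scene, path) {
  vis <- Filter(function(a) a@style@visible, scene@actors)
  geoms <- lapply(vis, function(a) list(
    name = a@name, kind = a@kind, color = a@style@color,
    alpha = a@style@alpha, source = a@source,
    vertices = round(as.vector(t(a@mesh@vertices)), 3),
    faces = as.vector(t(a@mesh@faces)) - 1L))
  doc <- list(background = scene@background,
              camera = list(position = scene@camera@position,
                            focalPoint = scene@camera@focalPoint,
                            viewup = scene@camera@viewup,
                            zoom = scene@camera@zoom),
              geometries = geoms)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\"><title>braincanvas scene</title>",
    "<style>body{margin:0;background:#111;color:#eee;font-family:sans-serif}",
    "canvas{display:block;margin:auto}</style></head><body>",
    "<canvas id=\"view\" width=\"900\" height=\"650\"></canvas>",
    "<script type=\"application/json\" id=\"scene-data\">",
    as.character(json),
    "</script>",
    "<script>",
    .HTML_VIEWER_JS,
    "</script></body></html>")
  ok <- tryCatch({ writeLines(html, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("cannot write HTML file: %s", path))
  invisible(path)
}

## minimal wireframe viewer embedded in exported documents
.HTML_VIEWER_JS <- paste(
  "const doc=JSON.parse(document.getElementById('scene-data').textContent);",
  "const cv=document.getElementById('view'),cx=cv.getContext('2d');",
  "let ang=0;function frame(){",
  "cx.fillStyle=doc.background;cx.fillRect(0,0,cv.width,cv.height);",
  "let all=[];doc.geometries.forEach(g=>{for(let i=0;i<g.vertices.length;i+=3)",
  "all.push(g.vertices.slice(i,i+3));});",
  "if(all.length){const c=[0,1,2].map(k=>all.reduce((s,v)=>s+v[k],0)/all.length);",
  "let r=1;all.forEach(v=>{const d=Math.hypot(v[0]-c[0],v[1]-c[1],v[2]-c[2]);",
  "if(d>r)r=d;});const s=0.45*Math.min(cv.width,cv.height)/r;",
  "const ca=Math.cos(ang),sa=Math.sin(ang);",
  "doc.geometries.forEach(g=>{cx.strokeStyle=g.color;cx.globalAlpha=Math.max(0.15,g.alpha);",
  "cx.beginPath();for(let i=0;i<g.faces.length;i+=3){",
  "const p=[g.faces[i],g.faces[i+1],g.faces[i+2]].map(ix=>{",
  "const v=g.vertices.slice(ix*3,ix*3+3);",
  "const x=(v[2]-c[2])*ca-(v[0]-c[0])*sa,y=v[1]-c[1];",
  "return[cv.width/2+x*s,cv.height/2+y*s];});",
  "cx.moveTo(p[0][0],p[0][1]);cx.lineTo(p[1][0],p[1][1]);",
  "cx.lineTo(p[2][0],p[2][1]);cx.closePath();}cx.stroke();});}",
  "ang+=0.01;requestAnimationFrame(frame);}frame();",
  sep = "\n")
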