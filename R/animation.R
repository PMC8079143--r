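## Keyframe animation: linear interpolation of camera pose and actor
## style parameters, frame-sequence rendering.
##
## Time grid convention: frames are sampled on the half-open grid
## [t0, t_end) at spacing 1/fps, so an animation spanning D seconds at
## F fps yields D*F frames when D*F is an integer (e.g. 3 s at 10 fps
## -> 30 frames). Interpolation is linear per scalar component between
## the keyframes where a parameter is defined; parameters absent from
## intermediate keyframes are carried through (step-hold), and
## non-numeric parameters (visibility) hold their previous value.

#' Create an animation over a scene
#'
#' @param scene a \linkS4class{BrainScene}.
#' @param fps frames per second (default 10).
#' @return A \linkS4class{SceneAnimation} with no keyframes.
#' @seealso [addKeyframe()], [stateAt()], [writeFrames()]
#' @export
sceneAnimation <- function(scene, fps = 10) {
  new("SceneAnimation", scene = scene, keyframes = list(),
      fps = as.numeric(fps))
}

#' Add a keyframe
#'
#' Keyframes are kept sorted by time; duplicate times are rejected.
#'
#' @param anim a \linkS4class{SceneAnimation}.
#' @param time keyframe time in seconds (>= 0).
#' @param camera optional \linkS4class{CameraPose} at this time.
#' @param actorParams optional named list: actor name -> list of style
#'   fields (alpha, color, visible) to key.
#' @return The updated animation.
#' @export
addKeyframe <- function(anim, time, camera = NULL, actorParams = list()) {
  stopifnot(is(anim, "SceneAnimation"))
  tms <- vapply(anim@keyframes, function(k) k@time, numeric(1))
  if (any(abs(tms - time) < 1e-12))
    stop(sprintf("duplicate keyframe time %g", time))
  if (length(actorParams)) {
    nms <- vapply(anim@scene@actors, function(a) a@name, character(1))
    unknown <- setdiff(names(actorParams), nms)
    if (length(unknown)) .unknownKeyStop(unknown[1], nms, "actor")
  }
  kf <- new("Keyframe", time = as.numeric(time), camera = camera,
            actorParams = actorParams)
  kfs <- c(anim@keyframes, list(kf))
  anim@keyframes <- kfs[order(vapply(kfs, function(k) k@time, numeric(1)))]
  validObject(anim)
  anim
}

## interpolate one track: times/values where the parameter is defined
.trackValue <- function(tms, vals, t, numericTrack = TRUE) {
  if (!length(tms)) return(NULL)
  if (t <= tms[1]) return(vals[[1]])
  if (t >= tms[length(tms)]) return(vals[[length(vals)]])
  i <- findInterval(t, tms)
  if (tms[i] == t) return(vals[[i]])
  if (!numericTrack) return(vals[[i]])      # step-hold
  f <- (t - tms[i]) / (tms[i + 1] - tms[i])
  vals[[i]] + f * (vals[[i + 1]] - vals[[i]])
}

#' Interpolated camera and actor parameters at a time
#'
#' Linear interpolation per scalar component between the bracketing
#' keyframes where each parameter is defined; the camera viewup is
#' renormalized after interpolation; colors interpolate in RGB; logical
#' parameters hold the previous keyframed value. At a keyframe time the
#' keyframe's values are reproduced exactly.
#'
#' @param anim a \linkS4class{SceneAnimation} with >= 1 keyframe.
#' @param time a time within [first keyframe, last keyframe].
#' @return list(camera = CameraPose-or-NULL, actorParams = named list).
#' @export
stateAt <- function(anim, time) {
  stopifnot(is(anim, "SceneAnimation"))
  tms <- vapply(anim@keyframes, function(k) k@time, numeric(1))
  if (!length(tms)) stop("animation has no keyframes")
  if (time < tms[1] - 1e-12 || time > tms[length(tms)] + 1e-12)
    stop(sprintf("time %g outside keyframe range [%g, %g]",
                 time, tms[1], tms[length(tms)]))
  ## camera track
  camIdx <- which(vapply(anim@keyframes, function(k) !is.null(k@camera),
                         logical(1)))
  camera <- NULL
  if (length(camIdx)) {
    ct <- tms[camIdx]
    cams <- lapply(anim@keyframes[camIdx], function(k) k@camera)
    pos <- .trackValue(ct, lapply(cams, function(c) c@position), time)
    foc <- .trackValue(ct, lapply(cams, function(c) c@focalPoint), time)
    vup <- .trackValue(ct, lapply(cams, function(c) c@viewup), time)
    zm <- .trackValue(ct, lapply(cams, function(c) c@zoom), time)
    camera <- cameraPose(pos, foc, .normalize(vup), zm)
  }
  ## actor parameter tracks, keyed by (actor, field)
  fieldsByActor <- list()
  for (k in anim@keyframes)
    for (an in names(k@actorParams))
      fieldsByActor[[an]] <- union(fieldsByActor[[an]],
                                   names(k@actorParams[[an]]))
  actorParams <- list()
  for (an in names(fieldsByActor)) {
    out <- list()
    for (fld in fieldsByActor[[an]]) {
      def <- which(vapply(anim@keyframes, function(k)
        !is.null(k@actorParams[[an]][[fld]]), logical(1)))
      vals <- lapply(anim@keyframes[def],
                     function(k) k@actorParams[[an]][[fld]])
      numericTrack <- fld != "visible"
      if (fld == "color")
        vals <- lapply(vals, function(v) .colorToUnit(normalizeColor(v)))
      v <- .trackValue(tms[def], vals, time, numericTrack)
      if (fld == "color")
        v <- grDevices::rgb(v[1], v[2], v[3])
      out[[fld]] <- v
    }
    actorParams[[an]] <- out
  }
  list(camera = camera, actorParams = actorParams)
}

## apply an interpolated state to a scene copy
.applyState <- function(scene, state) {
  if (!is.null(state$camera)) scene@camera <- state$camera
  nms <- vapply(scene@actors, function(a) a@name, character(1))
  for (an in names(state$actorParams)) {
    i <- match(an, nms)
    if (is.na(i)) next
    p <- state$actorParams[[an]]
    scene@actors[[i]] <- setStyle(scene@actors[[i]],
                                  color = p$color, alpha = p$alpha,
                                  visible = p$visible)
  }
  scene
}

#' Render an animation to a numbered frame sequence
#'
#' Frames are sampled at t0, t0 + 1/fps, ... on the half-open grid
#' [t0, t_end) and written as frame_00000.png, frame_00001.png, ...;
#' an external encoder (e.g. ffmpeg) can assemble them into a video.
#'
#' @param anim a \linkS4class{SceneAnimation} with >= 2 keyframes.
#' @param outDir output directory (created if missing).
#' @param width,height frame size in pixels (default 320 x 240).
#' @return Character vector of written frame paths.
#' @export
writeFrames <- function(anim, outDir, width = 320L, height = 240L) {
  stopifnot(is(anim, "SceneAnimation"))
  if (length(anim@keyframes) < 2L)
    stop("need at least 2 keyframes to generate frames")
  tms <- vapply(anim@keyframes, function(k) k@time, numeric(1))
  t0 <- tms[1]; tEnd <- tms[length(tms)]
  nF <- ceiling((tEnd - t0) * anim@fps - 1e-9)
  if (!dir.exists(outDir)) {
    ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create frame directory: %s", outDir))
  }
  paths <- character(nF)
  for (k in seq_len(nF)) {
    t <- t0 + (k - 1L) / anim@fps
    frame <- .applyState(anim@scene, stateAt(anim, t))
    paths[k] <- file.path(outDir, sprintf("frame_%05d.png", k - 1L))
    renderScreenshot(frame, paths[k], width = width, height = height)
  }
  paths
}
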