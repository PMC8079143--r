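## Actor construction and styling.

## default styles per actor kind (the atlas rgb overrides region color)
.DEFAULT_STYLES <- list(
  region      = list(color = "#aaaaaa", alpha = 0.3),
  points      = list(color = "salmon", alpha = 1),
  neuron_part = list(color = "#1f77b4", alpha = 1),
  streamlines = list(color = "#2ca02c", alpha = 0.8),
  volume      = list(color = "#d62728", alpha = 0.6),
  user_mesh   = list(color = "#aaaaaa", alpha = 1),
  probe       = list(color = "#333333", alpha = 1))

#' Construct an ActorStyle
#'
#' @param color color name, hex string or RGB triple (normalized to hex).
#' @param alpha opacity in [0, 1].
#' @param lineWidth positive line width in pixels.
#' @param visible logical.
#' @return An \linkS4class{ActorStyle}.
#' @export
actorStyle <- function(color = "#aaaaaa", alpha = 1, lineWidth = 1,
                       visible = TRUE) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  new("ActorStyle", color = normalizeColor(color), alpha = as.numeric(alpha),
      lineWidth = as.numeric(lineWidth), visible = isTRUE(visible))
}

#' Wrap data in renderable scene actors
#'
#' Dispatches on the payload/kind combination to the matching geometry
#' constructor: points become instanced sphere glyphs, streamlines become
#' tubes, a volume grid is thresholded and isosurfaced, a neuron
#' morphology yields one actor per part (soma, axon, dendrites, ...), and
#' a TriMesh is wrapped directly. The payload is never modified.
#'
#' @param payload a \linkS4class{TriMesh}, \linkS4class{BrainPoints},
#'   \linkS4class{NeuronMorphology}, \linkS4class{Streamlines} or
#'   \linkS4class{VolumeGrid}.
#' @param kind actor kind; defaults to the natural kind of the payload.
#' @param name actor name (parts get "<name>_<part>" names).
#' @param style an \linkS4class{ActorStyle}; kind-specific default when
#'   omitted.
#' @param source provenance string (file path or atlas acronym).
#' @param radius glyph/tube radius in micrometers for points and
#'   streamlines (defaults 25 and 10).
#' @param threshold iso-threshold for volume payloads (required there).
#' @param subdivisions sphere tessellation for points (default 1).
#' @return A single \linkS4class{SceneActor}, or a list of them for
#'   neuron morphologies.
#' @export
makeActor <- function(payload, kind = NULL, name = "actor", style = NULL,
                      source = "", radius = NULL, threshold = NULL,
                      subdivisions = 1L) {
  natural <- if (is(payload, "BrainPoints")) "points"
    else if (is(payload, "NeuronMorphology")) "neuron_part"
    else if (is(payload, "Streamlines")) "streamlines"
    else if (is(payload, "VolumeGrid")) "volume"
    else if (is(payload, "TriMesh")) "user_mesh"
    else stop("unsupported payload type: ", class(payload)[1])
  if (is.null(kind)) kind <- natural
  if (!kind %in% .ACTOR_KINDS)
    stop(paste("kind must be one of:", paste(.ACTOR_KINDS, collapse = ", ")))
  ## meshes may be wrapped as any kind (region/probe/user_mesh); data
  ## payloads must match their natural kind
  if (!is(payload, "TriMesh") && kind != natural &&
      !(natural == "points" && kind == "probe"))
    stop(sprintf("payload of type %s cannot be wrapped as kind '%s'",
                 class(payload)[1], kind))
  mkStyle <- function(k) {
    if (!is.null(style)) return(style)
    def <- .DEFAULT_STYLES[[k]]
    actorStyle(color = def$color, alpha = def$alpha)
  }
  if (is(payload, "NeuronMorphology")) {
    parts <- neuronToMeshes(payload)
    return(lapply(names(parts), function(p)
      new("SceneActor", name = paste(name, p, sep = "_"),
          kind = "neuron_part", mesh = parts[[p]], style = mkStyle(kind),
          source = source)))
  }
  mesh <- if (is(payload, "TriMesh")) payload
    else if (is(payload, "BrainPoints"))
      pointsToSpheres(payload, radius = if (is.null(radius)) 25 else radius,
                      subdivisions = subdivisions)
    else if (is(payload, "Streamlines"))
      streamlinesToMesh(payload, radius = if (is.null(radius)) 10 else radius)
    else if (is(payload, "VolumeGrid")) {
      if (is.null(threshold))
        stop("volume payloads require a 'threshold'")
      labelIsosurface(payload, threshold = threshold)
    }
  new("SceneActor", name = name, kind = kind, mesh = mesh,
      style = mkStyle(kind), source = source)
}

#' Update an actor's style fields
#'
#' Only the supplied fields change; everything else is preserved.
#'
#' @param actor a \linkS4class{SceneActor}.
#' @param color new color (name/hex/RGB triple), or NULL to keep.
#' @param alpha new opacity in [0, 1], or NULL to keep.
#' @param lineWidth new line width, or NULL to keep.
#' @param visible new visibility, or NULL to keep.
#' @return The updated \linkS4class{SceneActor}.
#' @export
setStyle <- function(actor, color = NULL, alpha = NULL, lineWidth = NULL,
                     visible = NULL) {
  stopifnot(is(actor, "SceneActor"))
  st <- actor@style
  if (!is.null(color)) st@color <- normalizeColor(color)
  if (!is.null(alpha)) {
    if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1)
      stop("alpha must be a single value in [0, 1]")
    st@alpha <- as.numeric(alpha)
  }
  if (!is.null(lineWidth)) {
    if (lineWidth <= 0) stop("lineWidth must be positive")
    st@lineWidth <- as.numeric(lineWidth)
  }
  if (!is.null(visible)) st@visible <- isTRUE(visible)
  validObject(st)
  actor@style <- st
  actor
}
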