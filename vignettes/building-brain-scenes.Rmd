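---
title: "Building and rendering brain scenes with braincanvas"
author: "braincanvas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and rendering brain scenes with braincanvas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincanvas)
```

## What the package models

Anatomically registered data -- labeled cell coordinates, neuron
morphologies, mesoscale projection streamlines, probe tracks, voxel-wise
expression volumes -- live in the coordinate space of a reference brain
atlas. An atlas bundles three things: a *structure tree* (the region
hierarchy, each region identified by a unique acronym and integer id),
an *annotation volume* (a 3D integer image whose voxel values are
structure ids, 0 outside the brain), and a store of per-region surface
meshes. braincanvas loads such bundles, answers hierarchy and spatial
queries against them, turns every supported data type into triangle
meshes, and composes the meshes into styled, renderable scenes.

All physical coordinates are micrometers on the axes
(anterior-posterior, dorsal-ventral, left-right), aligned with voxel
indices (i, j, k). Voxel i spans the half-open interval
[i - res, (i+1) - res), so a point maps to its voxel by floor division
and a point exactly on a boundary belongs to the higher-index voxel.
This single convention makes the spatial-query oracle (direct voxel
array indexing) unambiguous, and it is tested exhaustively.

Annotation volumes here label *leaf* regions only; membership in a
parent region (say, cortex) is resolved through the tree, mirroring
real atlases where parents are unions of their children. If a real
volume labels parents directly, `pointInRegion()` still works because
the queried region's own id is always in the accepted set.

## From voxels to surfaces

Region meshes that are not shipped with a bundle are built from the
annotation volume. The extractor:

1. selects the voxels of the region's own label plus all descendant
   labels (parents are unions of children);
2. supersamples the binary mask 2x by nearest neighbour, so that the
   0.5-level surface between inside and outside samples falls on the
   *voxel boundaries* rather than halfway between voxel centers;
3. pads the mask by one sample of zeros so selections touching the grid
   border still produce closed surfaces;
4. extracts the 0.5-level isosurface with marching tetrahedra on the
   Freudenthal (Kuhn) 6-tetrahedron decomposition of each grid cell.

The tetrahedral decomposition tiles space consistently, needs no
256-entry case table, and always yields watertight, consistently
oriented surfaces -- a hard requirement for the containment and volume
measurements downstream. The supersampling step is what keeps enclosed
volumes close to the voxel count times the voxel volume: a single
1 um voxel yields a closed mesh of about 0.71 um^3 (plain midpoint
extraction on the coarse grid would give 1/6 um^3, badly
underestimating small regions), and digital balls of radius 4, 8 and
16 voxels reproduce the analytic sphere volume with relative errors of
about 5%, 2% and 0.5% -- decreasing with size, as the acceptance suite
checks. Optional Laplacian smoothing (factor 0.5 per iteration, default
0 iterations) relaxes the staircase at a small cost in volume.

## Slicing with volume conservation

`sliceMesh()` clips a mesh against a plane and closes the cut. The
keep-side convention is fixed: `keep = "below"` retains points p with
(p - origin) . normal <= 0, i.e. the plane normal points into the
discarded half. Cut triangles are clipped into sub-triangles; the
directed cut edges are then capped with a fan from a single apex on the
cutting plane, oriented so that every boundary edge cancels. Because
the fan triangles carry signed volumes, the construction conserves
enclosed volume *exactly* (to floating point): kept plus complement
equals the original, which the tests verify to much better than the 1%
tolerance over random planes. Capping was chosen precisely because it
makes slicing testable through volume conservation.

## Glyphs, neurites, tubes

Cell coordinates become instanced icosphere glyphs (subdivision 1 = 42
vertices per sphere by default; the merged mesh has exactly N x 42
vertices). SWC morphologies are split by type code -- soma (1) spheres,
axon (2), basal dendrites (3), apical dendrites (4); codes outside 1-4
are accepted and grouped as "other" rather than rejected, since real
repositories use extended codes. Every parent-child segment becomes a
capped straight tube whose radius comes from the SWC record (or a
constant, selectable). Streamline polylines are swept with
parallel-transport frames into tubes with a 12-sided cross-section by
default -- a quality/size compromise; a 12-gon underestimates the
circular circumference by about 1.1%, well inside the tolerances the
measurements use. Straight tubes are exact prisms, which the neuron
tests exploit: total neurite length is recovered from tube volume
divided by the polygon cross-section area to better than 1%.

## Scenes, actors, rendering

A `BrainScene` is an ordered list of actors (order = render order,
stable), each with a name (made unique by suffixing at add time), a
kind, a mesh, and a style. Default styles: regions use the structure's
atlas rgb at alpha 0.3, the root reference actor is light gray at alpha
0.1, points are salmon -- defaults chosen to match common practice in
atlas visualization tools.

Screenshots are produced by an in-package software rasterizer:
orthographic projection through the scene camera, per-face Lambert
shading, global depth sort and back-to-front alpha compositing. This
trades photorealism for two properties the package promises: rendering
is fully headless (no display, no GPU) and *deterministic* -- two
renders of the same scene are pixel-identical, and the image always has
exactly the requested dimensions. Pixel-identity is only claimed within
one platform. Interactive windowing is not provided; the exported HTML
document (below) is the interactive channel. Camera presets "frontal",
"sagittal" and "top" are computed from the root bounding box.

`exportHTML()` writes a single self-contained file embedding every
visible actor's geometry and style in one JSON block, plus a small
inline canvas viewer; nothing references external assets, so the file
can be shared as-is.

## Animation

Keyframes hold a time, optionally a camera pose, and optionally
per-actor style parameters. Between the keyframes where a parameter is
defined, scalar components interpolate linearly (the camera viewup is
renormalized afterwards); parameters absent from intermediate keyframes
are carried through (step-hold), and after the last keyed value the
track holds. Logical parameters (visibility) always step. Linearity
was chosen as the baseline because no particular easing is canonical;
easing functions are a natural extension point.

Frames are sampled on the half-open grid [t0, t_end) at spacing 1/fps:
a D-second animation at F fps yields exactly D x F frames when D x F is
an integer (3 s at 10 fps = 30 frames), with no dangling extra frame at
the endpoint.

## The synthetic mini-atlas

`makeMiniAtlas()` writes a complete bundle with a five-node hierarchy
(root -> CTX -> {VISp, MOs}; TH under root) into a 48 x 36 x 40 voxel
grid at 25 um -- sizes chosen so every geometric property is measurable
in seconds while meshes still have tens of thousands of faces. Leaves
are mirrored ellipsoid pairs, which gives three useful ground truths:
exact left-right mirror symmetry of the annotation (checked voxel by
voxel), analytic centroids, and a mid-sagittal slice that halves the
root volume. Cells are sampled uniformly over a region's voxel mask, so
containment is true by construction; expression volumes use Gaussian
background (mean 10) vs hot region (mean 100, sd 6), so midpoint
thresholding recovers the hot mask essentially perfectly.

What the fixtures deliberately do not emulate: realistic neuroanatomy,
anisotropic resolutions, parent-labeled annotation volumes, and
non-watertight region meshes as found in some real atlas distributions.
Passing tests therefore demonstrate the correctness of the machinery,
not robustness to every real-world atlas dialect; the containment path
does handle open meshes by falling back to a flagged best-effort ray
parity result.

## Numerical choices and degenerate inputs

* Point-in-mesh uses ray parity with a fixed, slightly irrational ray
  direction, avoiding grazing hits on the axis-aligned facets that
  voxel-derived meshes are full of.
* Empty selections (a threshold above the global maximum, a region with
  neither mesh file nor labeled voxels) raise an "empty region" error;
  an empty *mesh* (everything sliced away) is a valid value, not an
  error, and such actors are simply hidden.
* Slicing classifies boundary vertices (signed distance exactly 0) as
  kept, so a plane tangent to a face does not duplicate geometry.
* Mesh orientation is normalized by flipping faces when the signed
  volume is negative; tube caps are wound opposite to their wall rings
  so the divergence-theorem volume is exact.
* Unknown acronyms, colors and actor names fail with nearest-match
  suggestions rather than bare errors.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile("atlas")
makeMiniAtlas(dir)                      # write a synthetic bundle
atlas <- loadAtlas(dir)                 # validate + load

ancestors(atlas, "VISp")$acronym        # "CTX" "root"
structureFromPoint(atlas, c(600, 450, 500))

scene <- brainScene(atlas)              # root reference actor + camera
scene <- addBrainRegion(scene, c("VISp", "MOs"), alpha = 0.5)
cells <- makeSyntheticCells(atlas, "VISp", 1000)
scene <- addActor(scene, makeActor(cells, name = "cells", radius = 10))
scene <- sceneSlice(scene, plane(c(600, 450, 500), c(0, 0, 1)),
                    actorNames = "root")
renderScreenshot(scene, "scene.png", width = 800, height = 600)
exportHTML(scene, "scene.html")

anim <- sceneAnimation(scene, fps = 10)
anim <- addKeyframe(anim, 0, camera = cameraPreset(scene, "frontal"))
anim <- addKeyframe(anim, 3, camera = cameraPreset(scene, "sagittal"))
writeFrames(anim, "frames")             # 30 numbered PNGs
```

## Known limitations

* The rasterizer is painter's-algorithm based: intersecting
  semi-transparent surfaces can blend in face-sort order rather than
  true per-pixel depth order. For the package's documentation-quality
  outputs this is invisible; for publication-grade figures the HTML
  export or an external renderer fed by `writeMeshFile()` is the route.
* `meshesIntersect()` reports surface contact and mutual containment;
  it is not a boolean CSG engine.
* NRRD/NIfTI volumes and networked atlas downloads are out of scope;
  the TIFF/OBJ/STL/SWC/NPY/CSV/JSON loaders define the interchange
  surface.
* Benchmark timings reported by `cmdBenchmark()` are wall-clock and
  hardware-dependent by nature; only its counts are reproducible.
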