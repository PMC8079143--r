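# braincanvas

Scene-based 3D visualization of anatomically registered neuroscience
data in R.

Modern anatomy pipelines register everything to a reference brain
atlas: cell coordinates detected in cleared tissue, single-neuron
reconstructions, mesoscale projection streamlines, implanted probe
tracks, voxel-wise gene expression. Turning those heterogeneous data
into a coherent 3D figure usually means stitching together an atlas
API, half a dozen file parsers, a mesh library and a renderer.
braincanvas packages that workflow for R users: load an atlas bundle,
query its hierarchy and annotation volume, drop data files into a
scene as styled *actors*, and export screenshots, shareable HTML
documents, or keyframe-animated frame sequences — all headless and
deterministic, with a synthetic mini-atlas generator so everything is
testable without downloads.

## The core machinery

**Atlas model.** An atlas is a structure tree (regions with unique
acronyms/ids, a single root, acyclic parent links), an annotation
volume *A* (a 3D integer image, `A[i,j,k]` = structure id, 0 outside
the brain), and a store of region meshes. Coordinates are micrometers
on (AP, DV, LR) axes; a point *p* maps to voxel `⌊p/res⌋`, so
`structureFromPoint` is exactly voxel-array indexing — and is tested
against that oracle. Annotation volumes label leaves; membership in a
parent region is resolved through the tree
(`pointInRegion(p, "CTX", includeSubstructures = TRUE)`).

**Voxels → surfaces.** Region meshes absent from the bundle are built
by isosurfacing the binary mask of the region's labels (own id +
descendants) at the 0.5 level: the mask is 2× supersampled so the
surface follows voxel boundaries, zero-padded so border regions close,
and triangulated by marching tetrahedra on the Freudenthal cell
decomposition — always watertight and consistently oriented. Digital
balls of radius 4/8/16 voxels reproduce (4/3)πr³ with relative errors
≈ 5% / 2% / 0.5%.

**Geometry toolkit.** Plane slicing with exact volume-conserving caps
(volume(below) + volume(above) = volume, to floating point); instanced
icosphere glyphs for point sets; SWC neurons as soma spheres + neurite
tubes grouped by type code; streamline tube sweeps; center-of-mass
distances, point-in-mesh ray-parity containment and mesh-mesh
intersection tests.

**Scenes and output.** Actors carry name, kind, mesh and style
(color/alpha/visibility). Screenshots come from an in-package software
rasterizer (orthographic camera, Lambert shading, painter's
compositing): exact requested pixel dimensions, no display needed, and
repeated renders are pixel-identical. `exportHTML` writes a single
self-contained document embedding every visible actor's geometry.
Keyframe animations interpolate camera pose and actor style linearly
and emit `frame_00000.png …` on the half-open time grid (3 s at
10 fps → exactly 30 frames).

## A worked example

```r
library(braincanvas)

dir <- tempfile("atlas")
makeMiniAtlas(dir)                   # synthetic bundle: hierarchy + labels + meshes
atlas <- loadAtlas(dir)
atlas
#> BrainAtlas 'braincanvas-mini': 5 structures, annotation 48x36x40 @ 25x25x25 um

ancestors(atlas, "VISp")$acronym
#> [1] "CTX"  "root"

m <- regionMesh(atlas, "VISp")
m
#> TriMesh: 10868 vertices, 21728 faces
#>   bounds (um): [775, 1050] x [350, 550] x [175, 825]
meshVolume(m)                        # 1.22e7 um^3, matching the labeled
                                     # voxel volume of 1.22e7 um^3

scene <- brainScene(atlas)                              # root reference actor
scene <- addBrainRegion(scene, c("VISp", "MOs"), alpha = 0.5)
cells <- makeSyntheticCells(atlas, "VISp", 1000, seed = 1)
scene <- addActor(scene, makeActor(cells, name = "cells", radius = 10))
scene
#> BrainScene with 4 actor(s) in atlas 'braincanvas-mini'
#>   - root [region] 64344 faces, alpha 0.10
#>   - VISp [region] 21728 faces, alpha 0.50
#>   - MOs [region] 21292 faces, alpha 0.50
#>   - cells [points] 80000 faces, alpha 1.00

all(pointInRegion(atlas, cells@coordinates, "CTX"))     # TRUE: VISp is in CTX

renderScreenshot(scene, "scene.png", width = 800, height = 600)
exportHTML(scene, "scene.html")

anim <- sceneAnimation(scene, fps = 10)
anim <- addKeyframe(anim, 0, camera = cameraPreset(scene, "frontal"))
anim <- addKeyframe(anim, 3, camera = cameraPreset(scene, "sagittal"))
writeFrames(anim, "frames")          # 30 numbered PNG frames
```

The same workflows run without writing R code through the CLI wrapper
(`inst/cli/braincanvas`): `render <config.json>`,
`query <atlas> <points> <region> [--substructures]`, and
`benchmark <atlas> [--sizes 1e3,1e4]`.

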