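Package: braincanvas
Title: Scene-Based 3D Visualization of Anatomically Registered Neuroscience Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Build, interrogate and render 3D scenes of anatomically
    registered data in a reference brain atlas space. Loads atlas bundles
    (structure hierarchy, annotation label volume, region meshes) and the
    standard neuroanatomy data formats (SWC neuron morphologies, OBJ/STL
    meshes, NPY/CSV cell coordinates, JSON tractography streamlines, TIFF
    volumes); answers hierarchy and point-in-region queries; converts label
    volumes to triangle meshes by isosurface extraction; composes actors
    into scenes with styles and cameras; renders deterministic off-screen
    screenshots; exports self-contained HTML documents; and interpolates
    keyframe animations into frame sequences. Ships a synthetic mini-atlas
    generator so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'io-swc.R'
    'io-mesh.R'
    'io-points.R'
    'io-streamlines.R'
    'io-volume.R'
    'isosurface.R'
    'mesh-ops.R'
    'atlas.R'
    'actors.R'
    'scene.R'
    'render.R'
    'animation.R'
    'fixtures.R'
    'cli.R'
    'zzz.R'
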