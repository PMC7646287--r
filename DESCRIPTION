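Package: neurofil
Title: Neuron Tracings from Filament-Tracer Surface Exports, Spine Mesh
    Repair and Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts surface-based neuron reconstructions exported by
    filament-tracing software (VRML files of unconnected tubular fragments
    sliced into 17-point elliptical sections) into hierarchical
    Neurolucida-style tracings with dendritic spine markers. Rebuilds the
    neurite tree from unconnected fragments by proximity search with an
    automatically calibrated connection threshold, builds somata from 2D
    contour stacks or from first-order neurite starting points, extracts
    and canonicalizes dendritic spine meshes into a reusable on-disk store,
    repairs and unifies fragmented spine meshes through a voxelization,
    morphological closing, Gaussian smoothing and isosurface extraction
    pipeline, compares meshes with sampled Hausdorff distances, and writes
    ASC, SWC, OBJ and PLY files. Includes a seeded synthetic-morphology
    generator used as a self-contained test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    xml2,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
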