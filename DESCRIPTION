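Package: voxray
Title: Multi-Volume Ray-Marching Renderer with Depth-Buffer Occlusion
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: CPU implementation of a multi-pass, depth-buffer-based
    multi-volume direct volume renderer for CT-style medical image data,
    as used in surgical planning. Volumes are divided into sub-volumes by
    an ad hoc 8-bit segmentation mask (sphere-brush painting), extracted
    into independent scene nodes, and rendered in consecutive ray-marching
    passes that share a per-pixel hit-distance depth buffer so that
    intersecting volumes occlude each other correctly. Includes
    screen-space bounding-rectangle culling, early ray termination,
    min-max empty-space skipping, gradient shading with a depth-only
    shadow-map pass, a one-pass reference renderer that samples every
    volume at every step, deterministic procedural phantoms (scoliotic
    spine, keyhole skull, fractured skull shell), NIfTI/NRRD/PNG/PFM
    input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    png,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
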