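Package: herd3d
Title: Multi-View Depth-Camera Reconstruction of Livestock Surfaces
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a single animal surface from a ring of synchronized
    depth cameras. Converts per-camera depth images to organized point clouds
    and grid-triangulated meshes, removes environment geometry (background
    subtraction against a cached environment capture, long-edge filtering,
    half-edge boundary erosion), calibrates camera extrinsics from a sphere
    target rig, and refines all camera poses by an interleaved optimization
    that alternates global surface reconstruction with per-camera Gauss-Newton
    point-to-plane alignment regularized toward the calibrated poses. Includes
    a synthetic multi-camera scene simulator (parametric animal body, fence
    occluders, ray-cast depth rendering) with ground-truth poses and labels,
    and a population-based global optimization baseline for comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0)
SystemRequirements: zlib
NeedsCompilation: yes
Config/testthat/edition: 3
RoxygenNote: 7.3.3
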