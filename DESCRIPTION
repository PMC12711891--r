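Package: skelsynth
Title: Synthetic Annotated Image Generation from Musculoskeletal Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Generates synthetic training images for human pose estimation from
    a simplified musculoskeletal model. Skeletal forward kinematics drive a
    procedurally generated, rigged and skinned human avatar; every rendered
    frame is annotated automatically with 2D/3D keypoints (pixel coordinates,
    Euclidean depth and ray-cast visibility labels), padded 2D bounding boxes,
    whole-body silhouette masks, per-segment masks and generalized-coordinate
    labels, and written out in a dataset layout with annotations and metadata
    CSV files. Includes an OpenSim .mot motion-file reader/writer, a pinhole
    camera model with randomized sampling, a software rasterizer, and quality
    control utilities for bounding-box step sensitivity and kinematics
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    jpeg,
    png,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
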