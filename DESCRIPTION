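Package: rosettecomplete
Title: Point-Cloud Completion and Growth-Trait Extraction for Top-View
    Rosette Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Completes single-view (top-down) colored point clouds of
    rosette plants such as lettuce, where leaf bases near the root crown
    are lost to self-occlusion, and extracts growth parameters from the
    completed clouds. The completion exploits the rosette growth habit:
    the root point is estimated from the plant centroid and the soil
    plane, leaves are segmented by color-based region growing, and each
    occluded outer leaf is repaired by uniform sampling between its
    root-facing edge and the root, with a mirror transform about the
    root-to-tip axis plus a hole-boundary fill for asymmetric leaves.
    Extracted traits are absolute and relative plant height, projected
    canopy area by grid occupancy, total leaf area by Gabriel-style
    greedy surface triangulation, and allometric volume and fresh-weight
    prediction from total leaf area. Includes an excess-green (ExG)
    imaging module for marker-calibrated reference areas and a synthetic
    rosette-scene generator with analytic ground truth and z-buffer
    occlusion so every stage is testable without sensor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
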