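Package: cagetrack
Title: Multi-Animal 3D Tracking and Home-Cage Behavior Analytics from
    Camera and Lidar Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs continuous, individually identified 3D
    trajectories of group-housed animals (designed around common
    marmoset family cages) by fusing multi-view video detections with
    lidar point-cloud cluster tracks.  Provides pinhole camera
    calibration from cage-corner fiducials, direct-linear-transform
    triangulation, voxel background subtraction and Euclidean cluster
    extraction with body-size gates, video-primary/lidar-fallback
    tracklet fusion, identity assignment from intermittent face
    recognition events, grooming-bout detection by Gaussian-smoothed
    detection frequencies, and downstream analytics (zone occupancy,
    place preference, inter-individual distances).  A scene simulator
    generates ground-truth trajectories and all synthetic sensor
    streams so every stage is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
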