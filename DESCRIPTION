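Package: kafr
Title: Kinematics-Adaptive Key-Frame Selection for Surgical Video Phase Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects key frames from tool-tracked surgical video by accumulating
    anchor-relative displacement (Adaptive 1) or velocity variation (Adaptive 2)
    of tracked tool centroids, with bisection calibration of the selection
    threshold to a target retention fraction. Includes ingestion of per-frame
    object detections (YOLO-style text or JSON-lines) into centroid tracks with
    class merging and screen-half hand assignment, uniform-sampling and
    pixel-MSE baseline selectors, the downstream phase-segmentation stages
    (per-phase frame rebalancing, sinusoidal positional encoding, combined
    cross-entropy plus Earth Mover's Distance loss, sliding-window temporal
    label smoothing, two-stream probability ensembling, accuracy and F1
    metrics), and a synthetic procedure simulator so the full pipeline is
    testable without any video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
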