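Package: arenatrack
Title: Multi-Camera Arena Tracking and Spatial Coding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tracking rodents across large arenas with overlapping
    overhead cameras and for analysing the spatial firing of simultaneously
    recorded neurons. Includes registration of multiple camera views to a
    common arena coordinate frame via RANSAC homography estimation,
    occlusion-robust two-LED position tracking (intensity threshold plus HSV
    colour segmentation, with per-camera detection followed by position
    averaging), TTL-based clock synchronization with interframe-interval
    jitter diagnostics, and a spatial-coding metric suite: occupancy-filtered
    rate maps, adaptive-binned Skaggs spatial information with cyclic-shuffle
    significance, place-field segmentation, head-direction tuning, and theta
    phase precession fits. A synthetic-data module generates foraging
    trajectories, rendered LED video, per-camera clocks and Poisson spike
    trains with known ground truth so the whole pipeline is testable without
    recording hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
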