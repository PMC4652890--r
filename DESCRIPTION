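Package: comanv
Title: Bio-Inspired Collision Avoidance from Translational Optic Flow
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-loop simulation of an insect-like flying agent that avoids
    collisions using spatial information extracted from translational optic
    flow on a spherical eye. Provides textured virtual flight arenas, a
    panoramic ray-casting renderer, correlation-type elementary motion
    detectors (Reichardt-Hassenstein), extraction of relative nearness maps
    from time-integrated squared flow, a saccadic steering controller built on
    the center-of-mass average nearness vector (COMANV), optional blending
    with a goal direction, and clustering of goal-directed trajectories into
    routes via Delaunay cell sequences, with reliability and path-efficiency
    metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
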