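Package: ht3dsnn
Title: Spiking Neural Implementation of the HT3D Hough Transform for
    Corner and Segment-Endpoint Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint detection of image corners and non-intersection line-segment
    endpoints with the HT3D Hough transform, implemented twice: as the regular
    array-based algorithm (two-stage voting in a (theta, d, p) parameter space
    followed by cell-pattern matching and coarse-to-fine localization) and as an
    event-driven network of leaky integrate-and-fire neurons whose spike trains
    reproduce the Hough vote counts exactly. Includes a deterministic
    event-driven spiking-network simulator, generators for synthetic edge
    scenes with exact ground truth, ground-truth matching metrics, and a small
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
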