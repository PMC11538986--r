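Package: nightshare
Title: Intergroup Sleeping-Site Sharing, Movement Coordination and Sleep
    Quality from GPS and Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for simultaneously tracked groups of
    social animals. Identifies discrete sleeping sites from nightly GPS
    centroids by hierarchical agglomerative clustering, estimates kernel
    utilization distributions and home-range overlap (including
    Bhattacharyya's affinity), infers the intergroup response radius from
    distance-binned movement coordination against day-shift permutation
    nulls, extracts and classifies dyadic intergroup interactions
    (merging, cohesive movement, front/behind positioning), and derives
    per-night sleep metrics (total sleep time, efficiency, fragmentation,
    onset/offset, dyadic synchronization) from tri-axial accelerometer
    bursts with a posture-angle classifier. A multi-group movement and
    accelerometry simulator with known ground truth supports validation
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    ggplot2,
    jsonlite,
    stats,
    tibble,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
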