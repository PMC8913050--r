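Package: acltis
Title: Tibial Insertion-Site Sensitivity of ACL Graft Force During Gait
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the force carried by a single-bundle anterior cruciate
    ligament (ACL) graft over a normalized gait cycle and quantifies how that
    force changes when the graft's tibial insertion site (TIS) is moved on the
    tibial plateau. The graft is a passive straight-line elastic element
    spanning configurable femoral and tibial insertion points across a
    three-rotation knee joint with flexion-coupled tibiofemoral translation.
    A seeded synthetic gait-kinematics generator provides per-subject knee
    flexion, adduction and internal-rotation waveforms calibrated to published
    landmark angles; a 13-position insertion-site sweep (center plus 2.5, 5.0
    and 7.5 mm anterior, posterior, medial and lateral offsets) yields
    101-point force curves that are summarised by stance-phase peak forces,
    Pearson correlation against the center condition, and paired t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
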