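Package: hfaccess
Title: Travel-Time Accessibility and Health-Workforce Coverage Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models geographic accessibility of primary health care over
    gridded landscapes. Builds a merged landcover friction surface from
    elevation, landcover, roads, rivers and lakes (rivers and lakes act as
    barriers unless a road crosses them), computes anisotropic least-cost
    travel time to the nearest health post or health center under
    configurable walking and motorized travel scenarios, delineates
    travel-time and cost-allocation catchments, and couples catchment
    populations with facility staffing tables to benchmark health-workforce
    availability (per-facility staffing minima, workforce density per
    10,000 population, and health-extension-worker gaps per district).
    Includes a seeded synthetic-scene generator so the whole pipeline is
    testable end to end, and referral analysis from health posts to their
    nearest health center with distance-based facility classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    yaml,
    digest,
    sp,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
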