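Package: phccost
Title: Activity-Based and Normative Costing of Primary Health Care Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An activity-based costing pipeline for primary health care (PHC)
    networks. Computes actual recurrent costs of sampled health posts, health
    centers, and primary hospitals (clinical labor allocated by staff time use,
    drugs and medical supplies by department tag or labor shares, indirect
    costs pooled), extrapolates sample costs to a regional facility network
    with three estimators (catchment-norm midpoints, reported catchments, and
    utilization-weighted expansion factors), derives normative costs from
    standard treatment protocols with population-in-need and coverage targets
    plus an overhead uplift, and quantifies the actual-versus-normative
    resource gap with one-way and best/worst-case sensitivity scenarios. A
    synthetic facility-survey generator with known ground truth makes every
    stage testable without access to confidential survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
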