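Package: i2s2r
Title: Interactive Infection Modelling of Online Rumor Engagement under
    Intervention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the I2S2R compartmental model of rumor engagement on a
    homogeneous social network: an ignorant class, two engager classes
    (supporters, who create and spread unverified content, and amplifiers, who
    only share it) and two immune classes with a relapse path from the
    amplifier-immune class back to supporters. The package provides the
    mean-field equations with stage-specific intervention adjustments,
    adaptive Runge-Kutta simulation with trajectory summaries (peak, peak
    time, extinction time), a registry of 24 hindering/persuasion intervention
    scenarios with benchmark comparison and dose-response analysis, numerical
    equilibrium location with local stability classification via the analytic
    Jacobian, and a density-based (DBSCAN) role-clustering analysis of
    per-user engagement features with a synthetic engager-table generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
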