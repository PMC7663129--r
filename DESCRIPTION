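Package: copmat
Title: Center-of-Pressure Excursion Analysis for Pressure-Sensitive Gait Mats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Measures center-of-pressure (COP) excursion during gait from
    time-stamped grids of activated cells recorded by a pressure-sensitive
    walkway. Provides footfall detection and foot-axis estimation with
    conversion of COP samples into a per-foot coordinate frame, detection of
    stance-phase events (midfoot-on, foot-flat, heel-off, midfoot-off) and
    subphase segmentation, temporal, spatial and velocity COP parameters,
    arch index computation from static footprints, and an intra-session
    reliability suite (two-way random absolute-agreement ICC, Spearman-Brown
    prophecy, coefficient of variation, standard error of measurement,
    minimal detectable change, required footfall counts). A synthetic
    heel-to-toe rollover generator with known ground truth makes the whole
    pipeline testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
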