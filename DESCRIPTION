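Package: nitroform
Title: Nitrogen-Form Acquisition Strategy from 15N Tracer Field Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing in-situ 15N labeling experiments that
    quantify how plants partition nitrogen acquisition between soil
    ammonium and nitrate. Implements the tracer computation chain from
    measured delta-15N signatures to actual uptake of pre-existing soil N
    (atom percent excess, 15N uptake and uptake rate, pool-dilution
    scaling, per-quadrat uptake), the derived strategy indices
    (proportional contributions, the preference index beta, and the
    percentage-similarity plasticity index), a forward simulator of the
    hierarchical field design (sites x habitats x quadrats x species x
    treatments) with known ground truth for parameter-recovery testing,
    and the comparison layer: rank-based inverse-normal and log
    transforms, assumption checks, one-way ANOVA with compact letter
    displays, t tests, a nested mixed-model screen, and standardized
    major axis (SMA) regression with common-slope, elevation, and shift
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
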