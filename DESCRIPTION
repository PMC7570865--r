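Package: firescar
Title: Accuracy Assessment of Burned-Area Maps Against Reference Fire Perimeters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for validating satellite-derived burned-area (BA) maps against
    reference fire perimeters on an equal-area grid. Rasterizes perimeter polygons
    with the maximum-area rule, computes annual burned-area percentages and their
    multi-year weighted averages, derives confusion-matrix accuracy metrics
    (overall accuracy, sensitivity, specificity, commission and omission errors)
    and the weighted total error, constructs Pareto boundaries of the minimal
    commission/omission error pairs achievable at degraded spatial resolutions,
    integrates the area under the Pareto boundary (AUPB) by the trapezoidal rule,
    and relates annual total errors to AUPB by linear regression. Includes a
    seeded synthetic fire-landscape generator so the whole pipeline can be
    exercised and tested without proprietary satellite data. Results are returned
    as tibbles; fitted objects support tidy() and glance(); result types have
    autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
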