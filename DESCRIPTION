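Package: vcmaxopt
Title: Optimal Photosynthetic Capacity Predicted from Climate
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts leaf photosynthetic capacity (the maximum rate of
    Rubisco carboxylation, Vcmax, and the maximum electron transport rate,
    Jmax, acclimated to growth temperature) from growing-season irradiance,
    air temperature, vapour pressure deficit, elevation and atmospheric CO2,
    by combining least-cost stomatal optimality (optimal Ci:Ca) with
    photosynthetic coordination theory (Rubisco-limited equals electron
    transport-limited assimilation) on Farquhar-von Caemmerer-Berry
    biochemistry. Includes the companion model-data evaluation toolkit:
    peaked-Arrhenius temperature standardization of field-measured Vcmax,
    half-degree grid-cell aggregation, Model II (standardized major axis)
    regression, percent-bias statistics with bias-versus-covariate multiple
    regressions, AIC model comparison and variance inflation factors, plus a
    seeded synthetic-data generator so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
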