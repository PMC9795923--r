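Package: phenomatch
Title: Cross-Platform Estimation and Comparison of Avian Migration Phenology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates spring and autumn migration phenology (half-maximum
    dates) from two complementary monitoring platforms: weather surveillance
    radar nightly passage rates and community-science weekly relative
    abundance surfaces. Converts radar reflectivity factor (dBZ) to
    reflectivity and migration traffic rates, aggregates weekly abundance
    within station buffers, fits penalized-spline seasonal smooths with year
    random effects, extracts half-max dates with early-peak fallback and
    retention filters, and compares the two platforms through correlations,
    offsets, flyway and order contrasts. Ships a seeded synthetic migration
    world with known ground truth so the full pipeline is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
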