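Package: easproj
Title: Long-Term Projection of Emergency Ambulance Service Demand
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Projects yearly emergency ambulance service (EAS) demand over
    multi-decade horizons by weighting base-year age-gender-specific demand
    with population-change indices derived from official population pyramids,
    and projects the U-shaped quadratic relationship between daily mean
    temperature and daily EAS demand with the same weights. Includes
    base-year screening with Grubbs' outlier test, demand profiling, a
    synthetic-data generator (population pyramids with stratum-specific
    growth, seasonal temperature series, Poisson patient records driven by
    temperature-dependent rates) for end-to-end validation without restricted
    records, and a report pipeline that exports the standard weight,
    projection, equation, trajectory and curve tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
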