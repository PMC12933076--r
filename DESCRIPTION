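Package: heatsrb
Title: Gestational Heat Exposure and the Sex Ratio at Birth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating the effect of gestational temperature
    exposure on the sex ratio at birth (SRB) from georeferenced birth
    records linked to gridded daily maximum temperature. Implements 5
    degree Celsius temperature-bin exposure construction over approximate
    gestational trimesters, a linear probability model with
    high-dimensional fixed effects absorbed by alternating within-group
    demeaning, one-way cluster-robust (CR1) sandwich inference, subgroup
    and placebo contrasts, translation of per-day coefficients into
    per-SD and SRB units, a warming-scenario projection engine, and a
    synthetic generator of DHS-like birth records and gridded climate
    with a configurable ground-truth temperature-sex response through
    both a prenatal-mortality and a sex-selective-abortion channel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    knitr
Config/testthat/edition: 3
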