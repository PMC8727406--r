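Package: bioheat
Title: Biometeorological Heat Stress, Heat Strain and Heat-Attributable
    Mortality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing the human impact of heat waves from hourly
    station weather. Computes the Universal Thermal Climate Index (UTCI) via
    the operational sixth-order polynomial approximation, estimates mean
    radiant temperature from cloud cover and solar geometry, evaluates a
    human heat-balance model (net heat storage, heart rate, sultriness
    index) and daily heat-stress/recovery time budgets, derives
    climatological heat indicators (hot-day counts, heat waves, anomalies
    in degrees and standard deviations), and models heat-attributable
    mortality (relative monthly mortality and strong-heat-related mortality
    rates). Includes a synthetic weather and mortality generator emulating
    Central European June conditions so that every stage of the pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
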