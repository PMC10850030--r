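Package: indoorheat
Title: Workplace Indoor Heat-Stress Projections from Neural Surrogates of
    Building Thermal Response
Version: 0.1.0
Authors@R:
    person("Analysis", "Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to project indoor thermal conditions at individual
    workplaces under climate-change scenarios. Per-workplace neural
    surrogates (single-hidden-layer perceptrons on lagged meteorological
    features) map outdoor weather to indoor air temperature and indoor
    physiologically equivalent temperature (PET, computed with a two-node
    MEMI heat-balance model). Scenario inputs are bias-corrected by
    quantile delta mapping against a historical reference, and heat-stress
    exposure is summarised as exceedance hours, heat days, consecutive-run
    durations and stress-class frequencies on a 365-day (noleap) calendar.
    A synthetic-data module generates outdoor weather, scenario variants
    with known imposed change, and indoor sensor-like series from a
    parameterised single-node building model, so the whole pipeline is
    testable offline with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
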