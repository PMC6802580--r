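Package: baleenIso
Title: Simulating Whale Movement and Baleen Carbon Isotope Profiles for
    Movement-Hypothesis Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring multi-year movement behaviour of baleen
    whales from stable carbon isotope profiles measured along baleen
    plates.  Provides a parametric synthetic ocean environment (monthly
    climatological POM d13C isoscape, SST, plankton biomass and
    bathymetry) with netCDF I/O, a daily agent-based whale movement
    model driven by behavioural state, temperature, depth and biomass,
    diet integration from phytoplankton baseline to baleen keratin,
    time calibration of incremental-tissue profiles by periodogram
    analysis of d15N cyclicity, and an ensemble regression framework
    that scores residency against migration hypotheses by comparing
    simulated and measured profiles.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    ncdf4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
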