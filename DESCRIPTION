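Package: pepsim
Title: Process-Based Simulation of Pepper Growth and Yield Under Heat Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily-timestep radiation-use-efficiency crop model for hot
    pepper (Capsicum annuum), with degree-day phenology, two-point S-curve
    leaf-area development, Beer's-law light interception, temperature, water
    and nitrogen stress, a soil water bucket with automatic irrigation, and
    harvest-index yield formation. Ships calibrated parameter sets for two
    accessions (PHR18, PHR23) under control and heat-stress conditions,
    calibration procedures (Kjeldahl total nitrogen, harvest index, nitrogen
    fractions, leaf-area-curve fitting, per-site potential-heat-unit and field
    radiation-use-efficiency estimation), a stochastic Korean-like weather
    generator, and a multi-site temperature-scenario engine for +3 to +5
    degree warming impact analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
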