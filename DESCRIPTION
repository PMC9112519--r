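Package: coldpmslt
Title: Proportional Multistate Lifetable Model of Cardiovascular Gains from
    Eradicating Cold Housing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the cardiovascular health gains (health-adjusted life
    years, HALYs) achievable by permanently warming cold homes, using a
    proportional multistate lifetable (pMSLT): a closed 2016 population is
    aged in annual cycles through a main all-cause lifetable coupled to
    parallel three-state disease lifetables for ischemic heart disease,
    ischemic stroke and haemorrhagic stroke. The cold-housing exposure acts
    on systolic blood pressure, which is converted into per-disease,
    per-age population impact fractions on incidence. Includes the base-year
    input tables, discounting and time-horizon reporting, Monte Carlo
    uncertainty propagation with correlated inputs, and a synthetic-data
    generator with known ground truth for validation.
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
    deSolve,
    optparse
Config/testthat/edition: 3
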