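Package: pbpksim
Title: Flow-Limited Physiologically Based Pharmacokinetic Model Simulation and Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Build, validate and simulate flow-limited physiologically based
    pharmacokinetic (PBPK) models with an arbitrary number of perfusion-limited
    tissue compartments connected to a central blood pool.  Supports
    intravenous-infusion exposure scenarios handled as dosing events, stiff ODE
    integration with a full mass-balance audit, closed-form steady-state
    analysis, lossless export to and re-import from SBML Level 3 with explicit
    unit definitions, packaged reference physiologies for adult men and women,
    a machine-checkable model-reporting checklist and a naming-convention
    linter for model components.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    xml2,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
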