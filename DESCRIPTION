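Package: vepsim
Title: Reduced-Order Simulation of a Self-Powered Venous Ejector Pump for
    Fontan Circulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Zero-dimensional (lumped-parameter) model of a passive venous
    ejector pump assisting the total cavopulmonary connection (Fontan)
    circulation. Represents device and junction geometry, enumerates the
    device design space, solves the coupled aortic-jet/venous-return network
    with a one-dimensional ejector momentum balance in assist and failure
    modes, tracks systemic arterial oxygen saturation through a shunt mixing
    model, and evaluates candidate designs against clinical selection
    criteria (aortic steal limit, saturation floors, fail-safe pressure
    preservation). Discharge coefficients and pathway loss coefficients are
    calibrated to published operating anchors so that desk-scale runs
    reproduce the reference hemodynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
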