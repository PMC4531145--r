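Package: ikedasim
Title: Whole-Body Simulation of Fluid, Electrolyte and Acid-Base Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of the classic Ikeda-type whole-body
    model of body-fluid, electrolyte, acid-base, respiratory and renal
    regulation for a healthy 55-kg adult male. Provides the model as pure
    algebraic/derivative functions over named physiological variables
    (uppercase mnemonics: QWU, XCO3, THDF, ...), a timed-protocol engine with
    stepwise input overrides and variable clamps, built-in scenarios (oral
    water loading, intravenous saline, CO2 inhalation, glucose tolerance,
    chronic respiratory acidosis and alkalosis with renal compensation),
    Davenport-diagram trajectory extraction, steady-state equilibration and
    mass-balance auditing, CSV/JSON serialization and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
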