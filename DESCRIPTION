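Package: mapkdesign
Title: Kinase-Phosphatase Interaction Designs and Sequestration in the
    MAPK Cascade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds and analyses deterministic models of the three-tier
    MAPK signalling cascade (MKKK -> MKK -> MK) under four experimentally
    observed kinase-phosphatase interaction designs (M1-M4), with
    Michaelis-Menten (K1), elementary mass-action (K2), and
    quasi-steady-state (K2_QSS) kinetics, in unsequestrated (USEQ) and
    phosphatase-sequestrated (PSEQ) conditions. Provides stiff ODE
    simulation under sustained or transient signal protocols, output
    metrics (amplitude, duration, memory), Latin-hypercube robustness
    analysis (total parameter variation and robustness coefficients),
    drivers for implicit-negative-feedback and dose-response experiments,
    and SBML import/export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
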