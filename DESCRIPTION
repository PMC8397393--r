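Package: ednasilica
Title: Analysis of Extracellular DNA Adhesion to Silica Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for three computational analyses of
    cation-mediated extracellular DNA (eDNA) adhesion to silica: processing
    of AFM single-molecule force spectroscopy curves (baseline estimation,
    alignment, onset detection, adhesion force, work of adhesion, rupture
    event census), radiolabel DNA-cell binding analysis (Langmuir and
    Scatchard fits, decay correction, molecules-per-cell and surface-coverage
    arithmetic), and molecular-dynamics trajectory post-processing
    (perpendicular charge-density profiles, centre-of-mass separations,
    cation-bridge census with lifetimes, adhesion energetics). A synthetic
    data module generates force curves, binding datasets and toy trajectories
    with analytic ground truth so every stage is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
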