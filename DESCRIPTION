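Package: coroflow
Title: Design and Simulation of Distal-Resistance Hardware for 3D-Printed
    Coronary Flow Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for benchtop coronary hemodynamics with 3D-printed
    patient-specific phantoms. Sizes distal-resistance catheters by the
    Hagen-Poiseuille law to emulate coronary capillary-bed resistance at
    rest and exercise, characterizes the intrinsic hydraulic resistance of
    outflow compliance chambers from constant-flow pressure sweeps, and
    solves a lumped-parameter (0D) model of the three-branch phantom flow
    circuit at steady state and as an RC transient. Includes a synthetic
    measurement generator with known ground truth for validating every
    estimator, and CSV/JSON report writers mirroring the bench protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), deSolve, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
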