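Package: lyosim
Title: Primary-Drying Simulation of Frozen Solutions in Tilted Cylindrical Vessels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale simulator of the primary-drying (sublimation) stage of
    freeze-drying for a frozen solution inside a cylindrical suspension-
    bioreactor vessel resting upright or tilted on the dryer shelf. Couples
    Hertz-Knudsen sublimation kinetics with the Murphy-Koop ice vapor-pressure
    correlation, quasi-steady Darcy vapor flow through the dried porous cake,
    and implicit heat conduction with a sublimation heat sink, on a voxelized
    representation of the tilted-cylinder fill geometry. Includes a reduced
    one-dimensional moving-front model, a freeze-drying cycle schedule, a
    single-parameter calibration of the evaporation coefficient, and the
    upright-versus-tilted orientation comparison experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
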