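Package: atheroIFEM
Title: Inverse Finite-Element Characterization of Atherosclerotic Plaque
    Tissues from Simulated IVUS Strain Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico framework for characterizing the mechanics of
    atherosclerotic plaque tissue from intravascular-ultrasound (IVUS) strain
    elastography. Generates parametric synthetic plaque cross-sections with
    eccentric lumina, lipid pools and calcifications, meshes them with
    conforming linear triangles, and inflates them with a plane-strain
    finite-element solver supporting linear elastic, Neo-Hookean and
    Gasser-Ogden-Holzapfel constitutive models under follower lumen pressure.
    Simulates two-pressure-frame IVUS measurements with additive noise at a
    target signal-to-noise ratio, and provides two inverse characterizations
    driven by a Generating-Set-Search pattern search: recovery of effective
    linear-elastic moduli at a working pressure, and recovery of full
    non-linear hyperelastic properties together with the zero-pressure
    configuration via a Pull-Back algorithm.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
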