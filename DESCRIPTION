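Package: adtorsion
Title: Angle-Damped Dihedral Torsion Potentials and Molecular Flexibility Models
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Class B (angle-damped) dihedral torsion model potentials for
    classical forcefields: elementary angle-damping functions built on the
    kangal proxy variable, the ADDT, CADT, ADCO, CACO and ADLD torsion model
    potentials including the torsion offset potential, directed-dihedral
    geometry utilities, torsion-scan projection onto orthonormal mode bases
    with smart mode selection, constrained-angle torsion-norm prediction,
    bounded least-squares force-constant fitting, and harmonic normal-mode
    vibrational analysis of assembled flexibility models. Includes fixture
    generators that rebuild small-molecule benchmark forcefields (isocyanic
    acid, hydrogen peroxide, acetylene) from tabulated internal coordinates
    and force constants.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
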