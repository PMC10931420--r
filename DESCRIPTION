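Package: kiwifem
Type: Package
Title: Multiscale Finite Element Analysis of Static Compression Damage in Kiwifruit
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for studying static compressive damage in
    kiwifruit. Converts uniaxial specimen force-displacement records to
    stress-strain curves and extracts Young's modulus, tangent modulus and
    bio-yield stress; builds a parametric multiscale fruit solid (skin
    membrane, transversely isotropic flesh, embedded core) with deterministic
    tetrahedral meshing; solves quasi-static displacement-controlled
    compression between two rigid plates with J2 elastoplasticity and
    penalty/Coulomb contact; and turns the resulting Von Mises fields into
    damage-volume fractions, damage-threshold forces and safe stacking
    counts. Includes seeded synthetic-data generators for specimen records
    and pseudo-experimental whole-fruit compression curves.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
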