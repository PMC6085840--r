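Package: plasmorec
Title: Fiber-Optic Surface Plasmon Resonance Recording of Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational model of a gold-coated multimode fiber sensor that
    transduces neuronal action potentials into optical absorption changes via
    surface plasmon resonance. Provides voltage-dependent Drude-Lorentz gold
    permittivity with a double-layer charge model, cross-section permittivity
    maps for three sensor geometries (fully removed cladding, half removed
    cladding, half removed core), a transfer-matrix multilayer engine with a
    multimode-fiber ray transmission model, a full-vector finite-difference
    eigenmode solver for the fiber cross-section, and an end-to-end pipeline
    computing absorption spectra versus electrode potential, voltage-induced
    peak shifts, and time-resolved intensity traces for synthetic action
    potentials.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
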