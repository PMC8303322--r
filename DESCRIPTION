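Package: langmuir2s
Title: Two-State Reorientation Model for Langmuir Monolayer Isotherms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical-mechanics model of Langmuir monolayers composed of
    surface-active molecules (drugs, peptides, sterols) that switch from a
    large-area horizontal orientation to a small-area vertical orientation
    under lateral compression. Implements the lattice-sublattice free energy,
    its constrained minimization for the equilibrium orientational
    distribution, surface pressure-area isotherms via implicit
    differentiation, inflection-point detection, and estimation of the
    reorientation energy (in units of thermal energy) from experimental
    isotherm landmarks or digitized curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
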