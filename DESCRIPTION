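Package: claypep
Title: Amino Acids and Peptides in Layered Double Hydroxide Interlayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular trajectories of amino acids and
    short peptides confined in hydrated layered double hydroxide (LDH)
    interlayers. Provides density-based layer assignment with d-spacing and
    undulation statistics, C-terminal adsorption fractions, radial
    distribution functions, backbone orientation histograms and reactive-pair
    counts, lateral diffusion analysis with a six-fold lattice-templating
    test, per-water hydration energetics, and a wetting-drying kinetic model
    of surface-activated peptide growth with deterministic and stochastic
    (Gillespie) solvers. A synthetic trajectory generator with controlled
    statistical structure makes every analysis stage testable without
    external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    optparse
Config/testthat/edition: 3
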