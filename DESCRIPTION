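Package: smlmchrom
Title: Single-Molecule Imaging Analysis of Pore Accessibility and
    Adsorption Kinetics in Chromatographic Particles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates and analyses in-situ single-molecule adsorption
    movies inside porous stationary-phase particles. Provides a synthetic
    movie generator (Poisson-distributed adsorption sites in an accessible
    elliptical shell, heterogeneous n-site first-order desorption kinetics,
    diffraction-limited Gaussian spots on a noisy camera), single-molecule
    localization with sub-pixel Gaussian fitting and super-resolution map
    reconstruction, particle-accessibility metrics (ellipse outline,
    depth-from-edge distributions in percent radius, the 99 percent
    accessible-depth limit, accessible-area ratio), dwell-time kinetics
    (event linking, site clustering, desorption rates, adsorption free
    energies), and elution-peak prediction from single-molecule dwell times
    via the compound-Poisson (Levy) stochastic theory of chromatography,
    including chromatographic peak moments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
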