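Package: PollenGM
Title: Gierer-Meinhardt Modeling of Pollen Aperture Patterning
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates pollen aperture patterning as a Gierer-Meinhardt
    activator-inhibitor reaction-diffusion system on a periodic ring (the
    pollen equator) and on the surface of a sphere (the microspore).
    Provides the homogeneous steady state, linear stability and Turing
    instability analysis with the dispersion relation, parameter-scaling
    robustness intervals, IMEX time integration from noise-perturbed
    initial conditions, transient and continuous spatial stimuli, a
    classifier mapping steady-state activator fields onto a taxonomy of
    spike patterns (equatorial, tetrahedral, polar, ring, spike-plus-ring,
    elongated), a synthetic labeled-field generator, and campaign drivers
    for domain-size, kinetics and stimulus sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, Matrix, igraph, jsonlite
Suggests: testthat (>= 3.0.0), pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
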