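Package: cwfdyn
Title: Conditional Wave Function Methods for Correlated Electron-Nuclear
    Quantum Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based quantum dynamics of model electron-nuclear systems
    with conditional wave functions (CWFs). Implements the stochastic
    interacting-CWF ansatz with a static conditional-eigenstate basis
    (sta-ICWF) as an imaginary-time eigensolver and a real-time propagator,
    and the trajectory-guided dynamical ICWF (dyn-ICWF) propagator in which
    one-body CWFs evolve under conditional Hamiltonians along Bohmian
    trajectories. Ships exact grid reference solvers (sparse Lanczos
    eigensolver, split-operator propagation, Born-Oppenheimer surface scans),
    a multi-trajectory Ehrenfest mean-field baseline, stochastic sampling of
    conditioning configurations, and observables (dipole response and
    delta-kick absorption spectra, reduced densities, adiabatic populations,
    decoherence indicator) for a family of soft-Coulomb model systems: a 1D
    hydrogen molecule, 1D electron-hydrogen scattering, the Shin-Metiu
    proton-coupled electron transfer model, and a 2D+2D conical-intersection
    model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
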