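Package: lvcdyn
Title: Surface-Hopping Nonadiabatic Dynamics on Linear Vibronic Coupling
    Potentials with Spin-Orbit Coupling
Version: 0.1.0
Authors@R: person("lvcdyn", "developers", role = c("aut", "cre"),
    email = "lvcdyn@example.org")
Description: Tools for simulating and analysing ultrafast photoinduced
    intersystem crossing and electron transfer with trajectory surface
    hopping on analytical linear vibronic coupling (LVC) potential energy
    surfaces.  The package evaluates diabatic LVC Hamiltonians and their
    adiabatic (spin-free MCH) and fully diagonal (spin-orbit-including)
    representations, samples Wigner initial conditions, selects initial
    electronic states from oscillator strengths in an excitation window,
    propagates fewest-switches surface-hopping trajectories with local
    diabatization, energy-based decoherence and full-velocity rescaling,
    and analyses ensembles in terms of electronic populations, fragment
    charge-transfer numbers, biexponential intersystem-crossing kinetics
    and normal-mode coherence descriptors.  A synthetic model generator
    emulating a rhenium-carbonyl/tryptophan charge-transfer manifold and
    exact quantum-dynamics oracles for small models support validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
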