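Package: membranepb
Title: Nonlinear Poisson-Boltzmann Electrostatics of Neuronal Membranes
Version: 0.1.0
Authors@R: person("Membrane", "Electrostatics Team", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Solves the equilibrium electrostatic potential profile across a
    four-region planar model of a neuronal membrane (extracellular bath,
    glycocalyx, lipid bilayer, cytoplasm) with mobile mono- and divalent
    electrolyte and fixed protein charges.  The nonlinear Poisson-Boltzmann
    equation is reduced to its first integral in each aqueous region,
    surface potentials at the three interfaces are obtained from Gauss-law
    jump conditions and the Helmholtz-Smoluchowski zeta potential via a
    fixed-point root search, and the full profile is assembled with
    fixed-step fourth-order Runge-Kutta integration.  Ships parameter
    presets for a healthy spinal ganglion neuron and a tumorous
    neuroblastoma cell in resting and action-potential states, plus
    charge-ratio sensitivity sweeps and a command-line driver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
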