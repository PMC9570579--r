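Package: PMMpKa
Title: Perturbed Matrix Method Estimation of Cysteine pKa from Classical
    Electrostatic Perturbations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes deprotonation Helmholtz free energies and pKa values of
    cysteine-like sites with the Perturbed Matrix Method (PMM): a gas-phase
    electronic Hamiltonian of a small quantum center (methanethiol /
    methanethiolate) is perturbed per molecular-dynamics frame by the classical
    electrostatic potential and field of the environment, re-diagonalized, and
    the resulting ground-state energy differences are turned into free-energy
    changes by exponential averaging and into pKa values through a
    thermodynamic cycle. Includes exogenous-electric-field and temperature
    scans, essential-dynamics PCA of C-alpha trajectories with planted-mode
    synthetic generators, and config-driven pipeline orchestration.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllGenerics.R'
    'AllClasses.R'
    'qc-io.R'
    'perturbation.R'
    'pmm-engine.R'
    'free-energy.R'
    'pka.R'
    'ed-analysis.R'
    'synthetic.R'
    'pipeline.R'
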