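# Fixture builders shared across test files. Everything is constructed in
# code; no stored binary data.

# Zero-perturbation frame for a quantum center.
zeroFrame <- function(qc) {
  n <- nAtoms(qc)
  PerturbationFrame(potentials = numeric(n), fields = matrix(0, n, 3),
                    potentialAtR0 = 0, fieldAtR0 = c(0, 0, 0))
}

# Uniform-potential frame (same V0 at every expansion center, zero fields).
uniformPotentialFrame <- function(qc, V0) {
  n <- nAtoms(qc)
  PerturbationFrame(potentials = rep(V0, n), fields = matrix(0, n, 3),
                    potentialAtR0 = V0, fieldAtR0 = c(0, 0, 0))
}

# Two-state single-atom toy with one transition dipole along x; closed-form
# eigenvalues (tr +/- sqrt(gap^2 + 4 h^2)) / 2.
toyTwoState <- function(gap = 100, mu01 = c(0.1, 0, 0)) {
  d <- array(0, c(2, 2, 3))
  d[1, 2, ] <- mu01
  d[2, 1, ] <- mu01
  QuantumCenter(
    speciesName = "toy", totalCharge = 0L,
    atoms = data.frame(label = "X", element = "C",
                       is_acidic_proton = FALSE),
    positions = matrix(0, 1, 3),
    energies = c(0, gap), charges = matrix(0, 2, 1), dipoles = d)
}

# Minimal hand-written qcdata v1 JSON (1 state, 2 atoms); returns the path.
writeMinimalQCJson <- function(path = tempfile(fileext = ".json")) {
  writeLines('{
  "species_name": "minimal",
  "total_charge": 0,
  "atoms": [
    {"label": "C1", "element": "C", "position": [0, 0, 0],
     "is_acidic_proton": false},
    {"label": "H1", "element": "H", "position": [0.1, 0, 0],
     "is_acidic_proton": true}
  ],
  "states": [
    {"index": 0, "energy0": 0.0, "atomic_charges": [-0.2, 0.2]}
  ],
  "dipoles": [
    {"i": 0, "j": 0, "vector": [0.05, 0, 0]}
  ]
}', path)
  path
}
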