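---
title: "Perturbed-matrix pKa estimation: models, assumptions and design choices"
author: "PMMpKa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbed-matrix pKa estimation: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PMMpKa)
```

## The model

PMMpKa estimates the deprotonation free energy and pKa of a cysteine-like
site by embedding a small quantum center (QC) — methanethiol for the
protonated species, methanethiolate for the deprotonated one — in the
classical electrostatics of a molecular-dynamics environment. The QC's
gas-phase electronic structure enters as data: unperturbed state energies,
per-state atomic charges from an ESP-style fit, and the matrix of
transition and permanent dipoles. Nothing quantum-chemical is computed
here; the package consumes those inputs (qcdata JSON, `readQuantumCenter()`)
and does the statistical mechanics.

Per frame, the perturbed Hamiltonian is assembled in the basis of
unperturbed states and re-diagonalized:

* **Diagonals** use the atom-based expansion truncated at the monopole
  term: $H_{ii} = E^0_i + \sum_N q_{N,i}\, V(R_N)$, with $V(R_N)$ the
  environment potential at each QC nucleus. Permanent dipoles are *not*
  added to the diagonal: for a spatially slowly varying field the
  per-state atomic charges already represent the state's charge
  distribution, and a uniform field enters the diagonal as
  $\sum_N q_{N,i}\,(-\mathbf{E}\cdot(R_N - r_0))$, which is exactly the
  charge representation of $-\mathbf{E}\cdot\mu_{ii}$. Adding $\mu_{ii}$
  explicitly would double-count. The residual intra-atomic dipole
  correction of the atom-based expansion is omitted because the data
  model carries no per-atom state dipoles; ESP charges absorb most of
  each atomic region's electrostatics.
* **Off-diagonals** use the dipolar approximation at the QC center of
  mass: $H_{ij} = -\mathbf{E}(r_0)\cdot\mu_{ij}$.

The ground-state energy gap between the two species in the *same*
environment frame, $\Delta U_e(t)$, is the microscopic quantity everything
downstream consumes. One environment trajectory supplies both species'
perturbations: the deprotonated form's heavy atoms inherit the potentials
and fields of their protonated counterparts through an explicit atom map
(`frameForDeprotonated()`), the acidic-proton site existing only in the
protonated species.

## Free energy and pKa

Two one-sided exponential averages bracket the deprotonation Helmholtz
free energy — the forward (protonated-ensemble) estimate from above, the
reverse (deprotonated-ensemble) estimate from below — and their midpoint
is reported. The midpoint construction assumes the ionic-environment
relaxation free energies of the two species cancel; the result object
records that assumption as a flag rather than pretending the terms were
computed. All exponential averages run in log-mean-exp form because
$\beta\,|\Delta U_e|$ reaches several hundred for condensed-phase
energies and naive exponentials overflow.

The thermodynamic cycle to pKa is
$\mathrm{p}K_a = (\Delta A + C)/(\ln 10\, k_B T)$ with
$C = \Delta\mu_{H^+} + \Delta G_{gas} + k_BT\ln(k_BT\rho^0/P) -
\Delta U_{el}^0$. Vibrational contributions to the solution- and
gas-phase deprotonation free energies are taken as equal and cancel; they
are documented, never evaluated. Because the individual constants are
rarely all available, the default operating mode *calibrates* $C$ from
one site of known pKa (`calibrateLumpedConstant()`; the aqueous cysteine
at 8.2 in the reference application). Differences between sites never
need $C$ at all: $\Delta\mathrm{p}K_a = (\Delta A_{site} -
\Delta A_{ref})/(\ln 10\, k_B T)$. The exact $\ln 10$ is used wherever
"2.303" appears in print — at the printed precision the two agree.

A note on temperature scans: published temperature tables of this kind
cannot generally be reproduced from their own $\Delta A$ column with a
single fixed reference, because the reference free energy is itself
temperature-dependent and per-temperature reference values are typically
not printed. `runTemperatureScan()` therefore evaluates its stated
formula with an explicit per-temperature reference (supplied or
recomputed), and makes no attempt to match tables whose reference values
are unavailable.

## Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| temperature | K | 300 | ambient-condition anchor; scans cover 300–350 K in 10 K steps |
| field magnitudes | V/nm | 0.00–0.12, step 0.02 | below ~0.02 V/nm effects vanish, above ~0.12 V/nm proteins denature quickly |
| field direction | unit vector | +z | lab frame is arbitrary for synthetic ensembles; configurable |
| reference pKa | — | 8.2 | aqueous cysteine, the calibration anchor |
| block count (uncertainty) | — | 10 | contiguous blocks per ensemble; quadrature midpoint propagation |
| Coulomb constant | kJ mol⁻¹ nm e⁻² | 138.935458 | fixed physics |
| field conversion | (kJ/mol/nm/e) per (V/nm) | 96.4853 | fixed physics |
| covariance divisor | — | T | population covariance; immaterial beyond ~10³ frames |

Units are fixed package-wide (energy kJ/mol, length nm, charge e, dipole
e·nm, converted to Debye only at reporting, 1 e·nm = 48.0321 D) to avoid
mixed-unit bugs against MD conventions.

## Electrostatics

`evaluateFrame()` performs a direct Coulomb sum over all environment
charges — no cutoff, no Ewald — with an optional minimum-image convention
when an orthorhombic box is given. Desk-scale environments are small
enough that the exact sum is both simplest and fastest to reason about;
periodic lattice summation is declared out of scope, and precomputed
potential/field tables can bypass the point-charge route entirely through
the tabular frame format.

The exogenous uniform field is added to every per-atom field and to the
field at $r_0$; each per-atom potential gains
$-\mathbf{E}_{ext}\cdot(R-r_0)$. Anchoring the potential gauge at the QC
center of mass matters: for a net-charged species (methanethiolate) an
absolute gauge constant would shift the energy unphysically, while the
$r_0$-anchored choice keeps the two species' energies comparable and makes
$V(r_0)$ exactly invariant — a property the tests assert. The scan
applies the field only inside the matrix construction; frames are not
re-sampled under the field, so field-induced conformational change is
explicitly outside what the scan captures.

## Essential dynamics

`fitAndCovariance()` superposes every frame onto a reference frame
(default: the first; least-squares translation + rotation via the Kabsch
SVD construction) and diagonalizes the $3N \times 3N$ covariance of the
flattened coordinates. The covariance is unweighted by default with
mass-weighted fitting available. Cross-projection of a second trajectory
into a reference subspace is supported (both fitted to the reference
structure and centered on the reference mean) so two conformational
ensembles can be compared in one plane; when a joint plane for two
ensembles is wanted, concatenating trajectories before the eigenanalysis
is the supported and default-recommended route.

Degenerate inputs are handled explicitly: an all-identical trajectory
yields an exactly zero spectrum, eigenvalues are clipped at zero against
roundoff, and eigenvector signs are fixed (largest-magnitude component
positive) so results are reproducible across LAPACK builds. The same
sign convention breaks degenerate Hamiltonian eigenpairs; no eigenvector
continuity tracking across frames is attempted because only ground-state
energies feed the free-energy layer.

## What the synthetic generators emulate — and what they do not

The generators stand in for the expensive inputs of a real study
(100 ns explicit-solvent MD, TDDFT electronic data):

* `genQuantumCenterPair()` produces structurally valid species pairs —
  correct charge sums per state, symmetric dipole arrays, strictly
  increasing energies, one acidic proton — with *no chemical realism*;
  correctness targets are invariants and identities, not spectroscopy.
* `genFieldFrames()` draws i.i.d. Gaussian potentials and fields per
  expansion center (optionally AR(1)-correlated, lag-one coefficient
  `phi`, marginal variance preserved) — a stationary caricature of
  environmental fluctuations without spatial correlation between atoms,
  solvent structure, or conformational substates.
* `genGaussianEnergyEnsembles()` gives the free-energy layer its analytic
  test bed: for Gaussian $\Delta U_e$ with equal means $\mu$ and variance
  $\sigma^2$, the forward and reverse estimators converge to
  $\mu \mp \beta\sigma^2/2$ and the midpoint to $\mu$ exactly.
* `genPlantedTrajectory()` builds the spiked-covariance model: known
  orthonormal mode directions (rigid-body components projected out, since
  superposition removes them), known variances, isotropic noise, optional
  random per-frame rigid-body motion. Internal motion is drawn before
  rigid transforms so the same seed yields identical internal
  displacements with and without rigid-body motion.

Passing tests on these ensembles demonstrates that the estimators and the
linear algebra are correct, deterministic and numerically stable. They do
*not* demonstrate force-field accuracy, sampling convergence of real
proteins, or the validity of the monopole truncation for a particular
chemical system — those depend on the real inputs a study supplies.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: $2\times10^5$ samples for
the Gaussian free-energy recovery (the closed form is then resolved to
about $\pm 0.01$ kJ/mol), 5000 frames and 20 atoms for planted-mode
recovery (variance within 5%, direction cosine > 0.99), 2000 frames,
seven states and six atoms for end-to-end pipeline runs. These are the
package's chosen study conditions for synthetic validation; all scale
linearly in frames if larger runs are wanted.

Numerical conventions worth knowing: exact spectral decomposition via
symmetric `eigen()`; matrices symmetrized as $(H+H^T)/2$ before
decomposition to shed roundoff; JSON serialization at 17 significant
digits so qcdata round trips are bit-exact; block uncertainties from 10
contiguous blocks propagated in quadrature to the midpoint (the
convention is configurable — error-bar provenance differs between
laboratories and is rarely stated).

## Known limitations

* The monopole-truncated diagonal ignores intra-atomic dipole
  corrections; systems where per-atom state dipoles matter need richer
  input data than the qcdata format carries.
* Periodic electrostatics (Ewald/PME) are not implemented; point-charge
  environments are summed directly.
* The exogenous-field scan perturbs energies, not ensembles: it cannot
  capture field-induced conformational change unless the supplied frames
  were themselves generated under the field.
* Absolute pKa values require either all cycle constants or a calibration
  reference; only pKa *differences* are reference-free.
* The interface is R functions plus config files; orchestration is
  `runCondition()` / `runFieldScan()` / `runTemperatureScan()` driven by
  plain lists or YAML, not a shell executable.
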