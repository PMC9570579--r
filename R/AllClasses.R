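## Central S4 data containers. Units are fixed package-wide:
## energy kJ/mol, length nm, charge e, dipole e.nm,
## potential kJ/(mol e), field kJ/(mol e nm).

# QuantumCenter ---------------------------------------------------------

#' QuantumCenter: electronic data of one chemical species
#'
#' Holds everything the perturbed-matrix construction needs about one
#' species of the deprotonation pair (methanethiol or methanethiolate in
#' the reference application): atoms with positions in the body frame,
#' unperturbed electronic state energies, per-state atomic charges from an
#' ESP-style fit, and the (transition and permanent) dipole matrix.
#'
#' States are stored sorted by unperturbed energy, index 1 = ground state.
#' Per-state atomic charges must sum to the species total charge; the
#' dipole array must be symmetric in its state indices; the stored center
#' of mass must match the mass-weighted mean of the atom positions.
#'
#' @slot speciesName Character, e.g. \code{"methanethiol"}.
#' @slot totalCharge Integer total charge in e.
#' @slot atoms \code{data.frame} with columns \code{label}, \code{element},
#'   \code{is_acidic_proton}.
#' @slot positions Numeric n_atoms x 3 matrix, nm, body frame.
#' @slot energies Numeric vector of unperturbed state energies, kJ/mol,
#'   ascending.
#' @slot charges Numeric n_states x n_atoms matrix of atomic charges, e.
#' @slot dipoles Numeric n_states x n_states x 3 array, e nm; entry
#'   \code{[i, j, ]} is the dipole matrix element between states i and j
#'   (diagonal = permanent dipoles).
#' @slot centerOfMass Numeric 3-vector, nm.
#'
#' @param speciesName,totalCharge,atoms,positions,energies,charges,dipoles
#'   See slots.
#' @param centerOfMass Optional; computed from positions and a built-in
#'   isotope-averaged mass table when omitted.
#'
#' @return \code{QuantumCenter()} returns a validated object.
#' @examples
#' pair <- genQuantumCenterPair(n_states = 3, n_atoms = 4, seed = 1)
#' qc <- protonated(pair)
#' nStates(qc)
#' stateEnergies(qc)
#' @aliases nStates nAtoms speciesName totalCharge atomPositions atomLabels
#'   stateEnergies stateCharges dipoleArray centerOfMass acidicProtonIndex
#' @export
setClass("QuantumCenter",
  representation(
    speciesName  = "character",
    totalCharge  = "integer",
    atoms        = "data.frame",
    positions    = "matrix",
    energies     = "numeric",
    charges      = "matrix",
    dipoles      = "array",
    centerOfMass = "numeric"
  )
)

setValidity("QuantumCenter", function(object) {
  msg <- character()
  na <- nrow(object@atoms)
  ns <- length(object@energies)
  if (!all(c("label", "element", "is_acidic_proton") %in% names(object@atoms)))
    msg <- c(msg, "atoms must have columns label, element, is_acidic_proton")
  if (!identical(dim(object@positions), c(na, 3L)))
    msg <- c(msg, "positions must be n_atoms x 3")
  if (!all(is.finite(object@positions)))
    msg <- c(msg, "positions must be finite")
  if (ns < 1L) msg <- c(msg, "at least one electronic state required")
  if (is.unsorted(object@energies))
    msg <- c(msg, "state energies must be sorted ascending")
  if (!identical(dim(object@charges), c(ns, na)))
    msg <- c(msg, "charges must be n_states x n_atoms")
  csum <- rowSums(object@charges)
  if (any(abs(csum - object@totalCharge) > 1e-6))
    msg <- c(msg, sprintf(
      "per-state atomic charges must sum to the total charge %d (worst sum %.8f)",
      object@totalCharge, csum[which.max(abs(csum - object@totalCharge))]))
  if (!identical(dim(object@dipoles), c(ns, ns, 3L)))
    msg <- c(msg, "dipoles must be n_states x n_states x 3")
  else {
    for (k in 1:3) {
      d <- object@dipoles[, , k, drop = FALSE]
      dim(d) <- c(ns, ns)
      if (max(abs(d - t(d))) > 1e-9) {
        msg <- c(msg, "dipole array must be symmetric in its state indices")
        break
      }
    }
  }
  nprot <- sum(object@atoms$is_acidic_proton)
  if (nprot > 1L) msg <- c(msg, "at most one acidic proton per species")
  com <- .massWeightedCenter(object@atoms$element, object@positions)
  if (max(abs(com - object@centerOfMass)) > 1e-6)
    msg <- c(msg, "centerOfMass does not match mass-weighted mean of positions")
  if (length(msg)) msg else TRUE
})

.massWeightedCenter <- function(elements, positions) {
  m <- atomicMass(elements)
  colSums(positions * m) / sum(m)
}

#' @rdname QuantumCenter-class
#' @export
QuantumCenter <- function(speciesName, totalCharge, atoms, positions,
                          energies, charges, dipoles, centerOfMass = NULL) {
  positions <- as.matrix(positions)
  dimnames(positions) <- NULL
  charges <- as.matrix(charges)
  dimnames(charges) <- NULL
  if (is.null(centerOfMass))
    centerOfMass <- .massWeightedCenter(atoms$element, positions)
  new("QuantumCenter",
      speciesName = as.character(speciesName),
      totalCharge = as.integer(totalCharge),
      atoms = atoms, positions = positions,
      energies = as.numeric(energies), charges = charges,
      dipoles = dipoles, centerOfMass = as.numeric(centerOfMass))
}

#' @rdname QuantumCenter-class
#' @export
setMethod("nStates", "QuantumCenter", function(x) length(x@energies))

#' @rdname QuantumCenter-class
#' @export
setMethod("nAtoms", "QuantumCenter", function(x) nrow(x@atoms))

#' @rdname QuantumCenter-class
#' @export
setMethod("speciesName", "QuantumCenter", function(x) x@speciesName)

#' @rdname QuantumCenter-class
#' @export
setMethod("totalCharge", "QuantumCenter", function(x) x@totalCharge)

#' @rdname QuantumCenter-class
#' @export
setMethod("atomPositions", "QuantumCenter", function(x) x@positions)

#' @rdname QuantumCenter-class
#' @export
setMethod("atomLabels", "QuantumCenter", function(x) x@atoms$label)

#' @rdname QuantumCenter-class
#' @export
setMethod("stateEnergies", "QuantumCenter", function(x) x@energies)

#' @rdname QuantumCenter-class
#' @export
setMethod("stateCharges", "QuantumCenter", function(x) x@charges)

#' @rdname QuantumCenter-class
#' @export
setMethod("dipoleArray", "QuantumCenter", function(x) x@dipoles)

#' @rdname QuantumCenter-class
#' @export
setMethod("centerOfMass", "QuantumCenter", function(x) x@centerOfMass)

#' @rdname QuantumCenter-class
#' @export
setMethod("acidicProtonIndex", "QuantumCenter", function(x) {
  idx <- which(x@atoms$is_acidic_proton)
  if (length(idx)) idx else NA_integer_
})

setMethod("show", "QuantumCenter", function(object) {
  cat("QuantumCenter:", object@speciesName,
      sprintf("(q = %+d e)\n", object@totalCharge))
  cat("  ", nAtoms(object), "atoms,", nStates(object), "electronic states\n")
  cat(sprintf("  ground-state energy %.4f kJ/mol\n", object@energies[1]))
})

# SpeciesPair -----------------------------------------------------------

#' SpeciesPair: protonated/deprotonated quantum centers with atom map
#'
#' Couples the protonated and deprotonated forms of the acid/base reaction
#' (CH3SH = CH3S- + H+). \code{atomMap} gives, for each deprotonated atom,
#' the index of the corresponding protonated atom; the map is injective and
#' never points at the acidic proton, so both species can be evaluated in
#' the same electrostatic environment.
#'
#' @slot protonated,deprotonated \code{QuantumCenter} objects.
#' @slot atomMap Integer vector, length \code{nAtoms(deprotonated)}.
#' @param protonated,deprotonated,atomMap See slots.
#' @param x A \code{SpeciesPair}.
#' @aliases protonated deprotonated atomMap
#' @export
setClass("SpeciesPair",
  representation(
    protonated   = "QuantumCenter",
    deprotonated = "QuantumCenter",
    atomMap      = "integer"
  )
)

setValidity("SpeciesPair", function(object) {
  msg <- character()
  p <- object@protonated
  d <- object@deprotonated
  if (p@totalCharge - d@totalCharge != 1L)
    msg <- c(msg, "protonated total charge must exceed deprotonated by 1 e")
  if (sum(p@atoms$is_acidic_proton) != 1L)
    msg <- c(msg, "protonated species must have exactly one acidic proton")
  if (any(d@atoms$is_acidic_proton))
    msg <- c(msg, "deprotonated species must have no acidic proton")
  if (length(object@atomMap) != nAtoms(d))
    msg <- c(msg, "atomMap must have one entry per deprotonated atom")
  if (anyDuplicated(object@atomMap))
    msg <- c(msg, "atomMap must be injective")
  if (any(object@atomMap < 1L | object@atomMap > nAtoms(p)))
    msg <- c(msg, "atomMap indices out of range")
  hp <- which(p@atoms$is_acidic_proton)
  if (length(hp) == 1L && hp %in% object@atomMap)
    msg <- c(msg, "atomMap must exclude the acidic proton")
  if (length(msg)) msg else TRUE
})

#' @rdname SpeciesPair-class
#' @export
SpeciesPair <- function(protonated, deprotonated, atomMap) {
  new("SpeciesPair", protonated = protonated, deprotonated = deprotonated,
      atomMap = as.integer(atomMap))
}

#' @rdname SpeciesPair-class
#' @export
setMethod("protonated", "SpeciesPair", function(x) x@protonated)

#' @rdname SpeciesPair-class
#' @export
setMethod("deprotonated", "SpeciesPair", function(x) x@deprotonated)

#' @rdname SpeciesPair-class
#' @export
setMethod("atomMap", "SpeciesPair", function(x) x@atomMap)

setMethod("show", "SpeciesPair", function(object) {
  cat("SpeciesPair:", object@protonated@speciesName, "=",
      object@deprotonated@speciesName, "+ H+\n")
})

# ChargeEnvironment -----------------------------------------------------

#' ChargeEnvironment: classical point charges perturbing the quantum center
#'
#' A set of environment point charges (protein + solvent in the reference
#' application) for one trajectory frame. An optional orthorhombic box
#' enables minimum-image displacement in the Coulomb sums.
#'
#' @slot positions Numeric N x 3 matrix, nm.
#' @slot charges Numeric vector of N charges, e.
#' @slot box Numeric length-0 (no box) or length-3 box edges, nm.
#' @param positions,charges,box See slots.
#' @export
setClass("ChargeEnvironment",
  representation(positions = "matrix", charges = "numeric", box = "numeric")
)

setValidity("ChargeEnvironment", function(object) {
  msg <- character()
  if (nrow(object@positions) != length(object@charges))
    msg <- c(msg, "positions and charges must have the same length")
  if (length(object@charges) && ncol(object@positions) != 3L)
    msg <- c(msg, "positions must have 3 columns")
  if (!length(object@box) %in% c(0L, 3L))
    msg <- c(msg, "box must be empty or length 3")
  if (length(object@box) == 3L && any(object@box <= 0))
    msg <- c(msg, "box edges must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname ChargeEnvironment-class
#' @export
ChargeEnvironment <- function(positions, charges, box = numeric()) {
  positions <- as.matrix(positions)
  if (length(charges) == 0L) positions <- matrix(numeric(), 0L, 3L)
  dimnames(positions) <- NULL
  new("ChargeEnvironment", positions = positions,
      charges = as.numeric(charges), box = as.numeric(box))
}

# PerturbationFrame -----------------------------------------------------

#' PerturbationFrame: electrostatics at the quantum-center expansion centers
#'
#' The electrostatic potential V and field E furnished by the environment at
#' every quantum-center atom position (used for the atom-based monopole
#' expansion of the diagonal Hamiltonian elements) and at the QC center of
#' mass r0 (used for the dipolar off-diagonal coupling).
#'
#' @slot potentials Numeric per-atom potential, kJ/(mol e).
#' @slot fields Numeric n_atoms x 3 field matrix, kJ/(mol e nm).
#' @slot potentialAtR0 Scalar potential at the center of mass.
#' @slot fieldAtR0 Numeric 3-vector field at the center of mass.
#' @param potentials,fields,potentialAtR0,fieldAtR0 See slots.
#' @export
setClass("PerturbationFrame",
  representation(
    potentials    = "numeric",
    fields        = "matrix",
    potentialAtR0 = "numeric",
    fieldAtR0     = "numeric"
  )
)

setValidity("PerturbationFrame", function(object) {
  msg <- character()
  if (!identical(dim(object@fields), c(length(object@potentials), 3L)))
    msg <- c(msg, "fields must be n_atoms x 3")
  if (length(object@potentialAtR0) != 1L || length(object@fieldAtR0) != 3L)
    msg <- c(msg, "r0 entries must be scalar potential and 3-vector field")
  vals <- c(object@potentials, object@fields, object@potentialAtR0,
            object@fieldAtR0)
  if (!all(is.finite(vals))) msg <- c(msg, "all entries must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname PerturbationFrame-class
#' @export
PerturbationFrame <- function(potentials, fields, potentialAtR0, fieldAtR0) {
  fields <- as.matrix(fields)
  dimnames(fields) <- NULL
  new("PerturbationFrame", potentials = as.numeric(potentials),
      fields = fields, potentialAtR0 = as.numeric(potentialAtR0),
      fieldAtR0 = as.numeric(fieldAtR0))
}

# PerturbationEnergySeries ----------------------------------------------

#' PerturbationEnergySeries: per-frame perturbed ground-state energy gaps
#'
#' The trajectory of dU_e = U_gs(deprotonated) - U_gs(protonated), both
#' perturbed ground-state energies evaluated in the same environment frame.
#' \code{ensembleLabel} records which species' environment trajectory
#' generated the frames ("protonated" or "deprotonated"); the free-energy
#' estimators use it to pick the sign convention.
#'
#' @slot ensembleLabel \code{"protonated"} or \code{"deprotonated"}.
#' @slot values Per-frame dU_e, kJ/mol.
#' @param ensembleLabel,values See slots.
#' @param x A \code{PerturbationEnergySeries}.
#' @aliases ensembleLabel energyValues
#' @export
setClass("PerturbationEnergySeries",
  representation(ensembleLabel = "character", values = "numeric")
)

setValidity("PerturbationEnergySeries", function(object) {
  msg <- character()
  if (!object@ensembleLabel %in% c("protonated", "deprotonated"))
    msg <- c(msg, "ensembleLabel must be 'protonated' or 'deprotonated'")
  if (length(object@values) < 1L)
    msg <- c(msg, "series must contain at least one frame")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "series values must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname PerturbationEnergySeries-class
#' @export
PerturbationEnergySeries <- function(ensembleLabel, values) {
  new("PerturbationEnergySeries", ensembleLabel = ensembleLabel,
      values = as.numeric(values))
}

#' @rdname PerturbationEnergySeries-class
#' @export
setMethod("ensembleLabel", "PerturbationEnergySeries",
          function(x) x@ensembleLabel)

#' @rdname PerturbationEnergySeries-class
#' @export
setMethod("energyValues", "PerturbationEnergySeries", function(x) x@values)

#' @rdname PerturbationEnergySeries-class
#' @export
setMethod("nFrames", "PerturbationEnergySeries", function(x) length(x@values))

setMethod("show", "PerturbationEnergySeries", function(object) {
  cat("PerturbationEnergySeries (", object@ensembleLabel, " ensemble): ",
      length(object@values), " frames, mean dU_e = ",
      sprintf("%.3f", mean(object@values)), " kJ/mol\n", sep = "")
})

# ThermoConfig ----------------------------------------------------------

#' ThermoConfig: temperature and derived thermodynamic factors
#'
#' @slot temperature Kelvin.
#' @slot kB Boltzmann constant, kJ/(mol K), fixed.
#' @slot beta 1/(kB T), mol/kJ.
#' @param temperature Kelvin, > 0.
#' @export
setClass("ThermoConfig",
  representation(temperature = "numeric", kB = "numeric", beta = "numeric")
)

setValidity("ThermoConfig", function(object) {
  if (object@temperature <= 0) "temperature must be positive" else TRUE
})

#' @rdname ThermoConfig-class
#' @export
ThermoConfig <- function(temperature = 300) {
  kB <- PMM_CONSTANTS$kB
  new("ThermoConfig", temperature = as.numeric(temperature), kB = kB,
      beta = 1 / (kB * temperature))
}

# FreeEnergyResult ------------------------------------------------------

#' FreeEnergyResult: exponential-average free-energy estimates
#'
#' Forward and reverse exponential-average (Zwanzig) estimates of the
#' deprotonation Helmholtz free-energy change, their midpoint, and a
#' block-averaging uncertainty. The forward estimate (protonated-ensemble
#' average) is an upper bound, the reverse (deprotonated-ensemble) a lower
#' bound; the reported delta A is their arithmetic mean, which relies on
#' the ionic relaxation free energies of the two species being equal
#' (recorded by \code{ionRelaxationAssumedEqual}).
#'
#' @slot forward,reverse kJ/mol.
#' @slot deltaA Midpoint, kJ/mol.
#' @slot uncertainty kJ/mol (block averaging, quadrature-propagated).
#' @slot nFramesProtonated,nFramesDeprotonated Frame counts.
#' @slot ionRelaxationAssumedEqual Logical documentation flag.
#' @slot blockEstimates List with per-block forward/reverse estimates.
#' @param x A \code{FreeEnergyResult}.
#' @aliases forwardEstimate reverseEstimate deltaA uncertainty
#' @export
setClass("FreeEnergyResult",
  representation(
    forward = "numeric", reverse = "numeric", deltaA = "numeric",
    uncertainty = "numeric",
    nFramesProtonated = "integer", nFramesDeprotonated = "integer",
    ionRelaxationAssumedEqual = "logical",
    blockEstimates = "list"
  )
)

setValidity("FreeEnergyResult", function(object) {
  if (abs(object@deltaA - (object@forward + object@reverse) / 2) > 1e-12 *
      max(1, abs(object@deltaA)))
    "deltaA must equal the midpoint of forward and reverse estimates"
  else TRUE
})

#' @rdname FreeEnergyResult-class
#' @export
setMethod("forwardEstimate", "FreeEnergyResult", function(x) x@forward)

#' @rdname FreeEnergyResult-class
#' @export
setMethod("reverseEstimate", "FreeEnergyResult", function(x) x@reverse)

#' @rdname FreeEnergyResult-class
#' @export
setMethod("deltaA", "FreeEnergyResult", function(x) x@deltaA)

#' @rdname FreeEnergyResult-class
#' @export
setMethod("uncertainty", "FreeEnergyResult", function(x) x@uncertainty)

setMethod("show", "FreeEnergyResult", function(object) {
  cat(sprintf(
    "FreeEnergyResult: deltaA = %.3f +/- %.3f kJ/mol\n", object@deltaA,
    object@uncertainty))
  cat(sprintf("  forward (upper) %.3f / reverse (lower) %.3f kJ/mol\n",
              object@forward, object@reverse))
  cat("  frames:", object@nFramesProtonated, "protonated /",
      object@nFramesDeprotonated, "deprotonated\n")
})

# CoordinateTrajectory --------------------------------------------------

#' CoordinateTrajectory: multi-frame coordinates for essential dynamics
#'
#' @slot coords Numeric T x N x 3 array, nm.
#' @slot atomLabels Character vector of N labels (residue + atom name).
#' @slot masses Optional numeric masses (length N or 0).
#' @param coords,atomLabels,masses See slots.
#' @param x A \code{CoordinateTrajectory}.
#' @aliases nFrames coordinates
#' @export
setClass("CoordinateTrajectory",
  representation(coords = "array", atomLabels = "character",
                 masses = "numeric")
)

setValidity("CoordinateTrajectory", function(object) {
  msg <- character()
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "coords must be a T x N x 3 array")
  else {
    if (d[1] < 2L) msg <- c(msg, "at least two frames required")
    if (d[2] < 1L) msg <- c(msg, "at least one atom required")
    if (length(object@atomLabels) != d[2])
      msg <- c(msg, "one label per atom required")
    if (!length(object@masses) %in% c(0L, d[2]))
      msg <- c(msg, "masses must be empty or one per atom")
  }
  if (!all(is.finite(object@coords)))
    msg <- c(msg, "coordinates must be finite")
  if (length(msg)) msg else TRUE
})

#' @rdname CoordinateTrajectory-class
#' @export
CoordinateTrajectory <- function(coords, atomLabels = NULL,
                                 masses = numeric()) {
  if (is.null(atomLabels)) atomLabels <- sprintf("ATOM%d", seq_len(dim(coords)[2]))
  new("CoordinateTrajectory", coords = coords,
      atomLabels = as.character(atomLabels), masses = as.numeric(masses))
}

#' @rdname CoordinateTrajectory-class
#' @export
setMethod("nFrames", "CoordinateTrajectory", function(x) dim(x@coords)[1])

#' @rdname CoordinateTrajectory-class
#' @export
setMethod("nAtoms", "CoordinateTrajectory", function(x) dim(x@coords)[2])

#' @rdname CoordinateTrajectory-class
#' @export
setMethod("coordinates", "CoordinateTrajectory", function(x) x@coords)

#' @rdname CoordinateTrajectory-class
#' @export
setMethod("atomLabels", "CoordinateTrajectory", function(x) x@atomLabels)

setMethod("show", "CoordinateTrajectory", function(object) {
  cat("CoordinateTrajectory:", dim(object@coords)[1], "frames x",
      dim(object@coords)[2], "atoms\n")
})

# EssentialSubspace -----------------------------------------------------

#' EssentialSubspace: eigen-decomposition of the positional covariance
#'
#' Result of fitting a trajectory (Kabsch superposition onto a reference
#' frame) and diagonalizing the 3N x 3N covariance of the fitted
#' coordinates. Eigenvalues (nm^2) are stored descending; eigenvectors are
#' orthonormal columns. The reference structure and mean structure are kept
#' so that further trajectories can be cross-projected into the same plane.
#'
#' @slot meanStructure N x 3 mean of the fitted frames, nm.
#' @slot referenceStructure N x 3 superposition reference, nm.
#' @slot eigenvalues 3N values, nm^2, descending.
#' @slot eigenvectors 3N x 3N orthonormal matrix.
#' @param x A \code{EssentialSubspace}.
#' @aliases eigenvalues eigenvectors meanStructure
#' @export
setClass("EssentialSubspace",
  representation(
    meanStructure      = "matrix",
    referenceStructure = "matrix",
    eigenvalues        = "numeric",
    eigenvectors       = "matrix"
  )
)

setValidity("EssentialSubspace", function(object) {
  msg <- character()
  n3 <- length(object@eigenvalues)
  if (any(object@eigenvalues < -1e-10))
    msg <- c(msg, "covariance eigenvalues must be non-negative")
  if (is.unsorted(rev(object@eigenvalues)))
    msg <- c(msg, "eigenvalues must be sorted descending")
  if (!identical(dim(object@eigenvectors), c(n3, n3)))
    msg <- c(msg, "eigenvector matrix must be 3N x 3N")
  else if (max(abs(crossprod(object@eigenvectors) - diag(n3))) > 1e-8)
    msg <- c(msg, "eigenvectors must be orthonormal")
  if (length(msg)) msg else TRUE
})

#' @rdname EssentialSubspace-class
#' @export
setMethod("eigenvalues", "EssentialSubspace", function(x) x@eigenvalues)

#' @rdname EssentialSubspace-class
#' @export
setMethod("eigenvectors", "EssentialSubspace", function(x) x@eigenvectors)

#' @rdname EssentialSubspace-class
#' @export
setMethod("meanStructure", "EssentialSubspace", function(x) x@meanStructure)

setMethod("show", "EssentialSubspace", function(object) {
  ev <- object@eigenvalues
  cat("EssentialSubspace:", length(ev) / 3, "atoms,",
      length(ev), "modes\n")
  cat(sprintf("  leading eigenvalues (nm^2): %s\n",
              paste(sprintf("%.4g", utils::head(ev, 3)), collapse = ", ")))
  tot <- sum(ev)
  if (tot > 0)
    cat(sprintf("  first two modes carry %.1f%% of the variance\n",
                100 * sum(utils::head(ev, 2)) / tot))
})
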