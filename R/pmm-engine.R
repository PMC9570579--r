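## Perturbed-matrix construction and diagonalization.
##
## Diagonal elements: atom-based monopole expansion
##   H_ii = E0_i + sum_N q_{N,i} V(R_N)
## Off-diagonal elements: dipolar approximation at the center of mass
##   H_ij = -E(r0) . mu_ij
## The intra-atomic dipole correction of the atom-based expansion is
## truncated: ESP-fit per-state atomic charges absorb most of each atomic
## region's electrostatics and no per-atom state dipoles are carried by
## the data model.

#' Build the perturbed electronic Hamiltonian for one frame
#'
#' @param qc A \code{\link{QuantumCenter}}.
#' @param frame A \code{\link{PerturbationFrame}} with one (V, E) entry per
#'   quantum-center atom.
#' @return A real symmetric n_states x n_states matrix, kJ/mol.
#' @examples
#' pair <- genQuantumCenterPair(n_states = 3, n_atoms = 4, seed = 1)
#' qc <- protonated(pair)
#' zero <- PerturbationFrame(numeric(4), matrix(0, 4, 3), 0, c(0, 0, 0))
#' buildHamiltonian(qc, zero)  # = diag(stateEnergies(qc))
#' @export
buildHamiltonian <- function(qc, frame) {
  if (length(frame@potentials) != nAtoms(qc))
    stop(sprintf(
      "frame has %d potential entries but quantum center has %d atoms",
      length(frame@potentials), nAtoms(qc)), call. = FALSE)
  ns <- nStates(qc)
  e0 <- frame@fieldAtR0
  H <- -(qc@dipoles[, , 1] * e0[1] + qc@dipoles[, , 2] * e0[2] +
           qc@dipoles[, , 3] * e0[3])
  dim(H) <- c(ns, ns)
  diag(H) <- stateEnergies(qc) + drop(stateCharges(qc) %*% frame@potentials)
  H
}

#' Diagonalize a perturbed Hamiltonian
#'
#' Exact spectral decomposition of the real symmetric matrix. Eigenvalues
#' are returned ascending; each eigenvector's sign is fixed so its
#' largest-magnitude component is positive.
#'
#' @param h Real symmetric matrix, kJ/mol.
#' @return A list with \code{eigenvalues} (ascending), \code{eigenvectors}
#'   (orthonormal columns), and \code{ground_energy} (smallest eigenvalue).
#' @export
diagonalizePerturbed <- function(h) {
  h <- as.matrix(h)
  if (nrow(h) != ncol(h) || max(abs(h - t(h))) > 1e-9)
    stop("Hamiltonian must be real symmetric", call. = FALSE)
  es <- eigen((h + t(h)) / 2, symmetric = TRUE)
  ord <- rev(seq_along(es$values))  # eigen() returns descending
  vals <- es$values[ord]
  vecs <- es$vectors[, ord, drop = FALSE]
  for (k in seq_len(ncol(vecs))) {
    m <- which.max(abs(vecs[, k]))
    if (vecs[m, k] < 0) vecs[, k] <- -vecs[, k]
  }
  list(eigenvalues = vals, eigenvectors = vecs, ground_energy = vals[1])
}

#' Perturbed ground-state energy of one species in one frame
#'
#' @param qc A \code{\link{QuantumCenter}}.
#' @param frame A \code{\link{PerturbationFrame}}.
#' @return Ground-state energy, kJ/mol.
#' @export
groundStateEnergy <- function(qc, frame) {
  diagonalizePerturbed(buildHamiltonian(qc, frame))$ground_energy
}

#' Derive the deprotonated species' frame from the protonated one
#'
#' A single environment trajectory supplies the perturbations for both
#' species: the shared heavy atoms of the deprotonated form receive the
#' potentials and fields of their protonated counterparts through the atom
#' map (the acidic-proton site exists only in the protonated species), and
#' the center-of-mass entries are shared.
#'
#' @param frame \code{\link{PerturbationFrame}} for the protonated species.
#' @param pair A \code{\link{SpeciesPair}}.
#' @return \code{\link{PerturbationFrame}} for the deprotonated species.
#' @export
frameForDeprotonated <- function(frame, pair) {
  m <- atomMap(pair)
  PerturbationFrame(
    potentials = frame@potentials[m],
    fields = frame@fields[m, , drop = FALSE],
    potentialAtR0 = frame@potentialAtR0,
    fieldAtR0 = frame@fieldAtR0)
}

#' Per-frame perturbed ground-state energy differences
#'
#' For every frame, both species' perturbed Hamiltonians are built and
#' diagonalized and the difference of ground-state energies
#' dU_e(t) = U_gs(deprotonated, t) - U_gs(protonated, t) is recorded.
#'
#' @param pair A \code{\link{SpeciesPair}}.
#' @param frames Either a list of \code{\link{PerturbationFrame}} objects
#'   for the protonated species (the deprotonated frames are derived via
#'   \code{\link{frameForDeprotonated}}), or a list of
#'   \code{list(protonated = , deprotonated = )} frame pairs.
#' @param label \code{"protonated"} or \code{"deprotonated"}: which
#'   species' environment trajectory generated the frames.
#' @return A \code{\link{PerturbationEnergySeries}}.
#' @export
perturbationEnergySeries <- function(pair, frames, label) {
  if (length(frames) < 1L) stop("at least one frame required", call. = FALSE)
  vals <- vapply(frames, function(fr) {
    if (is(fr, "PerturbationFrame")) {
      fp <- fr
      fd <- frameForDeprotonated(fr, pair)
    } else {
      if (is.null(fr$protonated) || is.null(fr$deprotonated))
        stop("frame pairs must carry 'protonated' and 'deprotonated' entries",
             call. = FALSE)
      fp <- fr$protonated
      fd <- fr$deprotonated
    }
    if (length(fp@potentials) != nAtoms(protonated(pair)))
      stop("missing perturbation at the acidic-proton site: protonated ",
           "frame must cover all ", nAtoms(protonated(pair)),
           " expansion centers", call. = FALSE)
    groundStateEnergy(deprotonated(pair), fd) -
      groundStateEnergy(protonated(pair), fp)
  }, numeric(1))
  PerturbationEnergySeries(ensembleLabel = label, values = vals)
}

#' Write a perturbation-energy series to CSV
#'
#' Two columns (frame, delta_Ue_kJ_per_mol) preceded by an ensemble-label
#' header line (\code{# ensemble_label: ...}).
#'
#' @param series A \code{\link{PerturbationEnergySeries}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeEnergySeries <- function(series, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ensemble_label: ", ensembleLabel(series)), con)
  utils::write.csv(
    data.frame(frame = seq_len(nFrames(series)),
               delta_Ue_kJ_per_mol = energyValues(series)),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a perturbation-energy series from CSV
#'
#' @param path Path written by \code{\link{writeEnergySeries}}.
#' @return A \code{\link{PerturbationEnergySeries}}.
#' @export
readEnergySeries <- function(path) {
  first <- readLines(path, n = 1L)
  label <- sub("^#\\s*ensemble_label:\\s*", "", first)
  tab <- utils::read.csv(path, comment.char = "#")
  PerturbationEnergySeries(ensembleLabel = label,
                           values = tab$delta_Ue_kJ_per_mol)
}
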