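## Per-frame electrostatics: direct Coulomb sums from point-charge
## environments, exogenous uniform fields, and tabular frame I/O.

#' Evaluate potential and field at the quantum-center expansion centers
#'
#' Direct Coulomb sum over all environment charges (no cutoff, no Ewald):
#' \deqn{V(R) = f \sum_k q_k / |R - r_k|, \quad
#'       E(R) = f \sum_k q_k (R - r_k) / |R - r_k|^3}
#' with \eqn{f = 138.935458} kJ mol\eqn{^{-1}} nm e\eqn{^{-2}}, evaluated
#' at every quantum-center atom position and at the center of mass r0.
#' When the environment carries an orthorhombic box, minimum-image
#' displacements are used.
#'
#' @param env A \code{\link{ChargeEnvironment}}.
#' @param qc A \code{\link{QuantumCenter}} supplying the expansion centers.
#' @return A \code{\link{PerturbationFrame}}.
#' @examples
#' pair <- genQuantumCenterPair(n_states = 2, n_atoms = 3, seed = 1)
#' env <- ChargeEnvironment(matrix(c(2, 0, 0), 1), charges = 1)
#' evaluateFrame(env, protonated(pair))
#' @export
evaluateFrame <- function(env, qc) {
  validObject(env); validObject(qc)
  centers <- rbind(atomPositions(qc), centerOfMass(qc))
  nC <- nrow(centers)
  V <- numeric(nC)
  E <- matrix(0, nC, 3L)
  if (length(env@charges)) {
    f <- PMM_CONSTANTS$coulomb
    box <- if (length(env@box) == 3L) env@box else NULL
    for (i in seq_len(nC)) {
      d <- sweep(-env@positions, 2L, -centers[i, ])  # R - r_k
      if (!is.null(box))
        d <- d - sweep(round(sweep(d, 2L, box, "/")), 2L, box, "*")
      r2 <- rowSums(d * d)
      if (any(r2 < 1e-12)) {
        k <- which.min(r2)
        stop(sprintf(
          "singularity: environment charge %d coincides with expansion center %d (distance %.2e nm)",
          k, i, sqrt(r2[k])), call. = FALSE)
      }
      r <- sqrt(r2)
      V[i] <- f * sum(env@charges / r)
      E[i, ] <- f * colSums(d * (env@charges / (r2 * r)))
    }
  }
  PerturbationFrame(potentials = V[seq_len(nC - 1L)],
                    fields = E[seq_len(nC - 1L), , drop = FALSE],
                    potentialAtR0 = V[nC], fieldAtR0 = E[nC, ])
}

#' Superpose an exogenous uniform electric field on a frame
#'
#' Adds a static, spatially uniform external field (in V/nm) to the
#' environmental electrostatics of a frame, mirroring the additive-term
#' treatment used when a constant field is applied during the MD. The
#' field is converted with 1 V/nm acting on 1 e = 96.4853 kJ/(mol nm) and
#' added to every per-atom field and to the field at r0; each per-atom
#' potential gains \eqn{-E_{ext} \cdot (R - r_0)}. The potential at r0 is
#' the gauge reference and stays unchanged, which keeps the energies of a
#' net-charged species well defined.
#'
#' @param frame A \code{\link{PerturbationFrame}}.
#' @param ext Numeric 3-vector, exogenous field in V/nm.
#' @param qc The \code{\link{QuantumCenter}} whose geometry defined
#'   \code{frame} (supplies atom positions and r0).
#' @return A new \code{\link{PerturbationFrame}}.
#' @export
applyExogenousField <- function(frame, ext, qc) {
  stopifnot(length(ext) == 3L, all(is.finite(ext)))
  eExt <- PMM_CONSTANTS$voltPerNm * as.numeric(ext)  # kJ/(mol e nm)
  rel <- sweep(atomPositions(qc), 2L, centerOfMass(qc))
  PerturbationFrame(
    potentials = frame@potentials - drop(rel %*% eExt),
    fields = sweep(frame@fields, 2L, eExt, "+"),
    potentialAtR0 = frame@potentialAtR0,
    fieldAtR0 = frame@fieldAtR0 + eExt)
}

# Tabular I/O -----------------------------------------------------------

#' Write perturbation frames to a tabular file
#'
#' One row per (frame, atom) with columns \code{frame, atom_label, V, Ex,
#' Ey, Ez}; the center-of-mass entries use the reserved label \code{"R0"}.
#' This format lets precomputed potential/field trajectories bypass
#' \code{\link{ChargeEnvironment}} entirely.
#'
#' @param frames A list of \code{\link{PerturbationFrame}} objects.
#' @param qc The \code{\link{QuantumCenter}} supplying atom labels.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @return Invisibly, \code{path}.
#' @export
writeFrameTable <- function(frames, qc, path, sep = "\t") {
  labs <- c(atomLabels(qc), "R0")
  rows <- lapply(seq_along(frames), function(t) {
    fr <- frames[[t]]
    data.frame(frame = t, atom_label = labs,
               V = c(fr@potentials, fr@potentialAtR0),
               Ex = c(fr@fields[, 1], fr@fieldAtR0[1]),
               Ey = c(fr@fields[, 2], fr@fieldAtR0[2]),
               Ez = c(fr@fields[, 3], fr@fieldAtR0[3]),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read perturbation frames from a tabular file
#'
#' @param path Path written by \code{\link{writeFrameTable}}.
#' @param sep Field separator (default tab).
#' @return A list of \code{\link{PerturbationFrame}} objects.
#' @export
readFrameTable <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("frame", "atom_label", "V", "Ex", "Ey", "Ez")
  if (!all(need %in% names(tab)))
    stop("frame table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  lapply(split(tab, tab$frame), function(blk) {
    r0 <- blk$atom_label == "R0"
    if (sum(r0) != 1L)
      stop("each frame block needs exactly one R0 row", call. = FALSE)
    at <- blk[!r0, , drop = FALSE]
    PerturbationFrame(
      potentials = at$V,
      fields = cbind(at$Ex, at$Ey, at$Ez),
      potentialAtR0 = blk$V[r0],
      fieldAtR0 = c(blk$Ex[r0], blk$Ey[r0], blk$Ez[r0]))
  })
}

#' Read a point-charge environment from an XYZQ text file
#'
#' Whitespace-separated \code{x y z q} per line (nm and e); blank lines
#' and \code{#} comments ignored.
#'
#' @param path Path to the XYZQ file.
#' @param box Optional orthorhombic box edges, nm.
#' @return A \code{\link{ChargeEnvironment}}.
#' @export
readChargeEnvironment <- function(path, box = numeric()) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("x", "y", "z", "q"))
  ChargeEnvironment(positions = as.matrix(tab[, 1:3]), charges = tab$q,
                    box = box)
}

#' Write a point-charge environment to an XYZQ text file
#'
#' @param env A \code{\link{ChargeEnvironment}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeChargeEnvironment <- function(env, path) {
  tab <- cbind(env@positions, env@charges)
  utils::write.table(tab, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
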