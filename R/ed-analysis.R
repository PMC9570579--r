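## Essential-dynamics PCA of C-alpha trajectories: Kabsch superposition,
## covariance diagonalization, projections, and auxiliary trajectory
## observables (per-atom eigenvector components, mean dipole moment,
## inter-residue distance, Pearson correlation).

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares translation + rotation of \code{P} onto \code{Q}
#' (no scaling, proper rotation enforced via the SVD determinant
#' correction).
#'
#' @param P,Q N x 3 coordinate matrices, nm.
#' @param weights Optional per-atom weights.
#' @return The transformed copy of \code{P}.
#' @keywords internal
kabschSuperpose <- function(P, Q, weights = NULL) {
  w <- if (is.null(weights)) rep(1, nrow(P)) else weights
  w <- w / sum(w)
  cp <- colSums(P * w)
  cq <- colSums(Q * w)
  Pc <- sweep(P, 2L, cp)
  Qc <- sweep(Q, 2L, cq)
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  sweep(Pc %*% t(R), 2L, -cq)
}

.fitFrames <- function(traj, reference, weights = NULL) {
  coords <- coordinates(traj)
  T_ <- dim(coords)[1]; N <- dim(coords)[2]
  X <- matrix(0, T_, 3L * N)
  for (t in seq_len(T_)) {
    fr <- kabschSuperpose(matrix(coords[t, , ], N, 3L), reference, weights)
    X[t, ] <- as.vector(t(fr))  # x1 y1 z1 x2 y2 z2 ...
  }
  X
}

#' Fit a trajectory and diagonalize its positional covariance
#'
#' Every frame is least-squares superposed (translation + rotation,
#' Kabsch) onto the reference frame; the covariance matrix of the
#' flattened 3N coordinates about their mean is diagonalized
#' (divisor T, population covariance). The leading eigenvectors span the
#' essential subspace of the dominant collective motions.
#'
#' @param traj A \code{\link{CoordinateTrajectory}}.
#' @param reference_frame_index Frame used as superposition reference
#'   (default 1).
#' @param mass_weighted Use the trajectory's masses as fitting weights
#'   (default FALSE, plain covariance).
#' @return An \code{\link{EssentialSubspace}}.
#' @examples
#' traj <- genPlantedTrajectory(n_atoms = 10, n_frames = 200,
#'                              mode_variances = 0.01, noise_sd = 0.002,
#'                              seed = 1)
#' sub <- fitAndCovariance(traj)
#' head(eigenvalues(sub), 3)
#' @export
fitAndCovariance <- function(traj, reference_frame_index = 1L,
                             mass_weighted = FALSE) {
  validObject(traj)
  coords <- coordinates(traj)
  N <- dim(coords)[2]
  weights <- if (mass_weighted && length(traj@masses)) traj@masses else NULL
  reference <- matrix(coords[reference_frame_index, , ], N, 3L)
  X <- .fitFrames(traj, reference, weights)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / nrow(X)
  es <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(es$values, 0)
  new("EssentialSubspace",
      meanStructure = matrix(mu, N, 3L, byrow = TRUE),
      referenceStructure = reference,
      eigenvalues = vals, eigenvectors = es$vectors)
}

#' Project a trajectory onto essential-subspace components
#'
#' Frames are fitted to the subspace's reference structure, centered on
#' the subspace's mean, and projected onto the requested eigenvectors.
#' Projecting the defining trajectory reproduces the eigenvalues as
#' per-component projection variances; projecting a second trajectory
#' into a reference subspace gives the cross-projection used to compare
#' conformational ensembles in one plane.
#'
#' @param traj A \code{\link{CoordinateTrajectory}} with the same atom
#'   count as the subspace.
#' @param subspace An \code{\link{EssentialSubspace}}.
#' @param components Integer indices of the components (default 1:2).
#' @return A T x k matrix of projections, nm.
#' @export
projectTrajectory <- function(traj, subspace, components = 1:2) {
  n3 <- length(eigenvalues(subspace))
  if (dim(coordinates(traj))[2] != n3 / 3L)
    stop("trajectory and subspace atom counts differ", call. = FALSE)
  if (any(components < 1L | components > n3))
    stop("component index out of range (1..", n3, ")", call. = FALSE)
  X <- .fitFrames(traj, subspace@referenceStructure)
  mu <- as.vector(t(subspace@meanStructure))
  Xc <- sweep(X, 2L, mu)
  proj <- Xc %*% eigenvectors(subspace)[, components, drop = FALSE]
  colnames(proj) <- paste0("PC", components)
  proj
}

#' Per-atom contribution to an essential-dynamics eigenvector
#'
#' Euclidean norm of each atom's (x, y, z) triplet within the requested
#' eigenvector; the squared norms sum to 1. Peaks locate the atoms that
#' dominate the collective motion (the active-site C-alpha atoms in the
#' reference application).
#'
#' @param subspace An \code{\link{EssentialSubspace}}.
#' @param component Eigenvector index.
#' @return Numeric vector of N per-atom norms.
#' @export
eigenvectorComponentsPerAtom <- function(subspace, component = 1L) {
  n3 <- length(eigenvalues(subspace))
  if (component < 1L || component > n3)
    stop("component index out of range", call. = FALSE)
  v <- eigenvectors(subspace)[, component]
  m <- matrix(v, ncol = 3L, byrow = TRUE)
  sqrt(rowSums(m^2))
}

#' Mean molecular dipole moment along a trajectory
#'
#' Per-frame dipole \eqn{\sum_i q_i (r_i - r_{ref})} with the geometric
#' center as reference point; for a neutral charge set the dipole is
#' independent of the reference, and for net-charged sets the geometric
#' center makes the convention explicit. The per-frame magnitudes are
#' averaged and reported in Debye (1 e nm = 48.0321 D).
#'
#' @param traj A \code{\link{CoordinateTrajectory}}.
#' @param charges Numeric vector of per-atom charges, e.
#' @return Mean dipole magnitude, Debye.
#' @export
meanDipole <- function(traj, charges) {
  coords <- coordinates(traj)
  N <- dim(coords)[2]
  if (length(charges) != N)
    stop("need one charge per atom", call. = FALSE)
  mags <- vapply(seq_len(dim(coords)[1]), function(t) {
    fr <- matrix(coords[t, , ], N, 3L)
    rel <- sweep(fr, 2L, colMeans(fr))
    sqrt(sum(colSums(rel * charges)^2))
  }, numeric(1))
  mean(mags) * PMM_CONSTANTS$eNmToDebye
}

#' Mean distance between two atom selections along a trajectory
#'
#' Per-frame Euclidean distance between the selections' centroids,
#' averaged over frames (e.g. the two active-site cysteine C-alpha atoms).
#'
#' @param traj A \code{\link{CoordinateTrajectory}}.
#' @param selection_a,selection_b Integer atom indices or a regular
#'   expression matched against the atom labels.
#' @return Mean distance, nm.
#' @export
residueDistance <- function(traj, selection_a, selection_b) {
  resolve <- function(sel) {
    idx <- if (is.character(sel)) grep(sel, atomLabels(traj)) else
      as.integer(sel)
    if (length(idx) == 0L)
      stop("empty atom selection: ", paste(sel, collapse = ","),
           call. = FALSE)
    idx
  }
  a <- resolve(selection_a); b <- resolve(selection_b)
  coords <- coordinates(traj)
  d <- vapply(seq_len(dim(coords)[1]), function(t) {
    fr <- matrix(coords[t, , ], dim(coords)[2], 3L)
    ca <- colMeans(fr[a, , drop = FALSE])
    cb <- colMeans(fr[b, , drop = FALSE])
    sqrt(sum((ca - cb)^2))
  }, numeric(1))
  mean(d)
}

#' Pearson product-moment correlation
#'
#' Thin checked wrapper around \code{stats::cor} for correlating scan
#' observables (e.g. mean dipole moments against free-energy changes).
#'
#' @param x,y Numeric vectors of equal length (>= 3) with nonzero
#'   variance.
#' @return Correlation coefficient in [-1, 1].
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need two equal-length vectors with at least 3 points",
         call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance input", call. = FALSE)
  stats::cor(x, y)
}

# Trajectory I/O --------------------------------------------------------

#' Write a trajectory as multi-frame XYZ (nm)
#'
#' @param traj A \code{\link{CoordinateTrajectory}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  coords <- coordinates(traj)
  N <- dim(coords)[2]
  con <- file(path, "w")
  on.exit(close(con))
  for (t in seq_len(dim(coords)[1])) {
    writeLines(c(as.character(N), sprintf("frame %d (nm)", t)), con)
    fr <- matrix(coords[t, , ], N, 3L)
    writeLines(sprintf("%s %.9g %.9g %.9g", atomLabels(traj),
                       fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ trajectory (nm)
#'
#' @param path Path written by \code{\link{writeTrajectoryXYZ}} (or any
#'   multi-frame XYZ whose coordinates are in nm).
#' @return A \code{\link{CoordinateTrajectory}}.
#' @export
readTrajectoryXYZ <- function(path) {
  lines <- readLines(path)
  frames <- list(); labels <- NULL; i <- 1L
  while (i <= length(lines)) {
    N <- as.integer(trimws(lines[i]))
    block <- lines[(i + 2L):(i + 1L + N)]
    tok <- strsplit(trimws(block), "[[:space:]]+")
    labels <- vapply(tok, `[`, character(1), 1L)
    xyz <- t(vapply(tok, function(v) as.numeric(v[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2L + N
  }
  T_ <- length(frames); N <- nrow(frames[[1]])
  coords <- array(0, c(T_, N, 3L))
  for (t in seq_len(T_)) coords[t, , ] <- frames[[t]]
  CoordinateTrajectory(coords, atomLabels = labels)
}
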