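## Synthetic-data generators with known ground truth: quantum-center
## pairs, Gaussian field/potential frame trajectories, Gaussian
## perturbation-energy ensembles, and planted-mode coordinate
## trajectories. Every generator is a pure function of its arguments
## (seed included) and produces objects that satisfy the target classes'
## invariants.

#' Generate a synthetic protonated/deprotonated quantum-center pair
#'
#' Builds a valid \code{\link{SpeciesPair}}: the protonated species has
#' \code{n_atoms} atoms (the last one the acidic proton), the
#' deprotonated species the same heavy atoms at identical positions;
#' per-state atomic charges sum exactly to 0 (protonated) and -1
#' (deprotonated); unperturbed energies are strictly increasing with
#' electronic-excitation-scale gaps; the dipole array is symmetric with
#' transition/permanent dipoles of a few tenths of an e nm. The geometry
#' and electronic parameters are structurally valid but not chemically
#' realistic — ground truth for invariant and identity tests, not
#' spectroscopy.
#'
#' @param n_states Number of electronic states (default 7: ground + six
#'   excited).
#' @param n_atoms Number of atoms of the protonated species (default 6,
#'   methanethiol-sized), >= 2.
#' @param seed Integer seed; identical seeds give identical pairs.
#' @return A validated \code{\link{SpeciesPair}}.
#' @examples
#' pair <- genQuantumCenterPair(seed = 1)
#' pair
#' @export
genQuantumCenterPair <- function(n_states = 7L, n_atoms = 6L, seed = 1L) {
  stopifnot(n_states >= 1L, n_atoms >= 2L)
  set.seed(seed)
  elements <- c("C", "S", rep("H", n_atoms - 2L))
  labels <- make.unique(elements, sep = "")
  positions <- matrix(stats::rnorm(3L * n_atoms, sd = 0.08), n_atoms, 3L)

  mkQC <- function(name, total, na, pos, ele, lab, acid) {
    gaps <- abs(stats::rnorm(n_states - 1L, mean = 400, sd = 80)) + 50
    energies <- cumsum(c(0, gaps))
    charges <- matrix(stats::rnorm(n_states * na, sd = 0.3), n_states, na)
    charges <- charges - (rowSums(charges) - total) / na  # exact charge sum
    dip <- array(0, c(n_states, n_states, 3L))
    for (i in seq_len(n_states)) for (j in i:n_states) {
      v <- stats::rnorm(3L, sd = 0.15)
      dip[i, j, ] <- v; dip[j, i, ] <- v
    }
    QuantumCenter(
      speciesName = name, totalCharge = total,
      atoms = data.frame(label = lab, element = ele,
                         is_acidic_proton = acid, stringsAsFactors = FALSE),
      positions = pos, energies = energies, charges = charges,
      dipoles = dip)
  }

  prot <- mkQC("methanethiol-like (synthetic)", 0L, n_atoms, positions,
               elements, labels,
               c(rep(FALSE, n_atoms - 1L), TRUE))
  heavy <- seq_len(n_atoms - 1L)
  deprot <- mkQC("methanethiolate-like (synthetic)", -1L, n_atoms - 1L,
                 positions[heavy, , drop = FALSE], elements[heavy],
                 labels[heavy], rep(FALSE, n_atoms - 1L))
  SpeciesPair(prot, deprot, atomMap = heavy)
}

#' Generate Gaussian potential/field frame trajectories
#'
#' Emulates the stationary fluctuating electrostatics an MD environment
#' exerts on the quantum center: independent Gaussian potential and field
#' components per frame and per expansion center, with the requested
#' moments. An optional AR(1) autocorrelation (lag-one coefficient
#' \code{phi}, stationary marginal variance preserved) makes
#' block-averaging error estimation nontrivial. The deprotonated species'
#' frames are derived from the protonated ones through the atom map
#' (one environment, two solutes).
#'
#' @param pair A \code{\link{SpeciesPair}}.
#' @param n_frames Number of frames.
#' @param mean_potential,sd_potential Moments of the per-atom potential,
#'   kJ/(mol e).
#' @param mean_field 3-vector mean field, kJ/(mol e nm).
#' @param sd_field Per-component field standard deviation.
#' @param phi AR(1) lag-one autocorrelation in [0, 1) (default 0,
#'   i.i.d. frames).
#' @param seed Integer seed.
#' @return A list of \code{list(protonated = , deprotonated = )}
#'   \code{\link{PerturbationFrame}} pairs.
#' @export
genFieldFrames <- function(pair, n_frames, mean_potential = 0,
                           sd_potential = 1,
                           mean_field = c(0, 0, 0), sd_field = 1,
                           phi = 0, seed = 1L) {
  stopifnot(n_frames >= 1L, sd_potential >= 0, all(sd_field >= 0),
            phi >= 0, phi < 1)
  set.seed(seed)
  na <- nAtoms(protonated(pair))
  nch <- na + 1L  # atoms + r0
  sdF <- rep_len(sd_field, 3L)

  ar1 <- function(n, sd) {
    if (sd == 0) return(numeric(n))
    if (phi == 0) return(stats::rnorm(n, sd = sd))
    x <- numeric(n)
    x[1] <- stats::rnorm(1L, sd = sd)
    innov <- stats::rnorm(n - 1L, sd = sd * sqrt(1 - phi^2))
    for (t in 2:n) x[t] <- phi * x[t - 1L] + innov[t - 1L]
    x
  }

  V <- matrix(0, n_frames, nch)
  for (c_ in seq_len(nch)) V[, c_] <- mean_potential + ar1(n_frames, sd_potential)
  E <- array(0, c(n_frames, nch, 3L))
  for (c_ in seq_len(nch)) for (k in 1:3)
    E[, c_, k] <- mean_field[k] + ar1(n_frames, sdF[k])

  lapply(seq_len(n_frames), function(t) {
    fp <- PerturbationFrame(
      potentials = V[t, seq_len(na)],
      fields = matrix(E[t, seq_len(na), ], na, 3L),
      potentialAtR0 = V[t, nch], fieldAtR0 = E[t, nch, ])
    list(protonated = fp, deprotonated = frameForDeprotonated(fp, pair))
  })
}

#' Generate Gaussian perturbation-energy ensembles
#'
#' Draws the two ensembles' per-frame energy gaps from normal
#' distributions: protonated-labelled series ~ N(mu_prot, sigma^2),
#' deprotonated ~ N(mu_deprot, sigma^2). For equal means mu the Gaussian
#' free-energy identity gives closed-form expectations for the
#' exponential estimators — forward mu - beta sigma^2 / 2, reverse
#' mu + beta sigma^2 / 2, midpoint mu — making this the analytic test bed
#' for \code{\link{helmholtzDeltaA}}.
#'
#' @param mu_prot,mu_deprot Ensemble means, kJ/mol.
#' @param sigma Common standard deviation, kJ/mol, >= 0.
#' @param n_frames Frames per ensemble.
#' @param phi Optional AR(1) lag-one autocorrelation (default 0).
#' @param seed Integer seed.
#' @return A list with elements \code{protonated} and \code{deprotonated}
#'   (\code{\link{PerturbationEnergySeries}}).
#' @export
genGaussianEnergyEnsembles <- function(mu_prot = 10, mu_deprot = 10,
                                       sigma = 2, n_frames = 1000L,
                                       phi = 0, seed = 1L) {
  stopifnot(sigma >= 0, n_frames >= 1L, phi >= 0, phi < 1)
  set.seed(seed)
  draw <- function(mu) {
    if (sigma == 0) return(rep(mu, n_frames))
    if (phi == 0) return(stats::rnorm(n_frames, mean = mu, sd = sigma))
    x <- numeric(n_frames)
    x[1] <- stats::rnorm(1L, sd = sigma)
    innov <- stats::rnorm(n_frames - 1L, sd = sigma * sqrt(1 - phi^2))
    for (t in 2:n_frames) x[t] <- phi * x[t - 1L] + innov[t - 1L]
    mu + x
  }
  list(
    protonated = PerturbationEnergySeries("protonated", draw(mu_prot)),
    deprotonated = PerturbationEnergySeries("deprotonated", draw(mu_deprot)))
}

#' Generate a coordinate trajectory with planted collective modes
#'
#' Frames are built as base structure + sum_m a_m(t) u_m + noise with
#' mode amplitudes a_m ~ N(0, v_m) along orthonormal 3N-dimensional
#' directions u_m, plus isotropic Gaussian noise — the spiked-covariance
#' model whose principal components are known by construction. Optional
#' random rigid-body motion per frame exercises the superposition step.
#'
#' @param n_atoms Number of atoms.
#' @param n_frames Number of frames.
#' @param mode_directions Optional 3N x m matrix of mode directions
#'   (orthonormalized internally; random orthonormal directions when
#'   omitted).
#' @param mode_variances Numeric vector of m mode variances, nm^2.
#' @param noise_sd Isotropic per-coordinate noise standard deviation, nm.
#' @param base_structure Optional N x 3 base geometry (random when
#'   omitted).
#' @param rigid_body Add a random rotation + translation to every frame
#'   (default FALSE).
#' @param seed Integer seed.
#' @return A \code{\link{CoordinateTrajectory}} with attribute
#'   \code{"planted"} carrying the true directions and variances.
#' @export
genPlantedTrajectory <- function(n_atoms = 20L, n_frames = 1000L,
                                 mode_directions = NULL,
                                 mode_variances = 0.01,
                                 noise_sd = 0.01,
                                 base_structure = NULL,
                                 rigid_body = FALSE, seed = 1L) {
  stopifnot(n_atoms >= 1L, n_frames >= 2L, all(mode_variances >= 0),
            noise_sd >= 0)
  set.seed(seed)
  n3 <- 3L * n_atoms
  m <- length(mode_variances)
  if (is.null(base_structure))
    base_structure <- matrix(stats::rnorm(n3, sd = 1), n_atoms, 3L)
  if (is.null(mode_directions))
    mode_directions <- matrix(stats::rnorm(n3 * m), n3, m)
  mode_directions <- as.matrix(mode_directions)
  if (ncol(mode_directions) != m)
    stop("need one direction per mode variance", call. = FALSE)
  ## Project out rigid-body motions (3 translations + 3 infinitesimal
  ## rotations about the base structure): the superposition step removes
  ## them, so planted internal modes must be orthogonal to that subspace.
  rigid <- .rigidBodyBasis(base_structure)
  mode_directions <- mode_directions - rigid %*%
    crossprod(rigid, mode_directions)
  qr_ <- qr(mode_directions)
  if (qr_$rank < m || any(abs(diag(qr.R(qr_))[seq_len(m)]) < 1e-8))
    stop("planted mode directions must be linearly independent after ",
         "projection out of rigid-body motions", call. = FALSE)
  U <- qr.Q(qr_)[, seq_len(m), drop = FALSE]

  ## Internal motion is drawn first, rigid-body transforms afterwards, so
  ## the same seed yields the same internal displacements with and
  ## without rigid-body motion (the fitting step should then recover
  ## identical covariance spectra).
  amp <- matrix(stats::rnorm(n_frames * m), n_frames, m) %*%
    diag(sqrt(mode_variances), m)
  noise <- matrix(stats::rnorm(n_frames * n3, sd = noise_sd), n_frames, n3)
  base_flat <- as.vector(t(base_structure))
  coords <- array(0, c(n_frames, n_atoms, 3L))
  for (t in seq_len(n_frames)) {
    x <- base_flat + drop(U %*% amp[t, ]) + noise[t, ]
    coords[t, , ] <- matrix(x, n_atoms, 3L, byrow = TRUE)
  }
  if (rigid_body) {
    for (t in seq_len(n_frames)) {
      R <- .randomRotation()
      coords[t, , ] <- sweep(coords[t, , ] %*% t(R), 2L,
                             -stats::rnorm(3L, sd = 0.5))
    }
  }
  traj <- CoordinateTrajectory(
    coords, atomLabels = sprintf("CA%d", seq_len(n_atoms)))
  attr(traj, "planted") <- list(directions = U, variances = mode_variances)
  traj
}

## Orthonormal basis of the 6-dimensional rigid-body subspace (flattened
## x1 y1 z1 ... ordering) at a given structure.
.rigidBodyBasis <- function(structure) {
  n <- nrow(structure)
  centered <- sweep(structure, 2L, colMeans(structure))
  B <- matrix(0, 3L * n, 6L)
  for (k in 1:3) B[seq(k, 3L * n, by = 3L), k] <- 1
  for (i in seq_len(n)) {
    r <- centered[i, ]
    rows <- (3L * (i - 1L) + 1L):(3L * i)
    B[rows, 4L] <- c(0, -r[3], r[2])
    B[rows, 5L] <- c(r[3], 0, -r[1])
    B[rows, 6L] <- c(-r[2], r[1], 0)
  }
  qr_ <- qr(B)
  qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
}

.randomRotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  Q <- qr.Q(qrd)
  Q <- Q %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
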