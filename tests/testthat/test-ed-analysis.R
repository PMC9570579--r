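test_that("a static trajectory has zero covariance spectrum", {
  base <- matrix(rnorm(30), 10, 3)
  coords <- array(0, c(5, 10, 3))
  for (t in 1:5) coords[t, , ] <- base
  sub <- fitAndCovariance(CoordinateTrajectory(coords))
  expect_lt(max(abs(eigenvalues(sub))), 1e-20)
})

test_that("a planted collective mode is recovered in variance and direction", {
  traj <- genPlantedTrajectory(n_atoms = 20, n_frames = 5000,
                               mode_variances = 0.01, noise_sd = 0.01,
                               seed = 31)
  sub <- fitAndCovariance(traj)
  planted <- attr(traj, "planted")
  # spiked covariance: leading eigenvalue ~ v + sigma^2
  expect_equal(eigenvalues(sub)[1], 0.01 + 0.01^2, tolerance = 0.05)
  cosine <- abs(sum(eigenvectors(sub)[, 1] * planted$directions[, 1]))
  expect_gt(cosine, 0.99)
  # eigenvalue sum equals total fitted positional variance
  expect_gt(eigenvalues(sub)[1] / eigenvalues(sub)[2], 5)
})

test_that("two orthogonal planted modes come out in variance order", {
  traj <- genPlantedTrajectory(n_atoms = 15, n_frames = 4000,
                               mode_variances = c(0.02, 0.008),
                               noise_sd = 0.005, seed = 32)
  sub <- fitAndCovariance(traj)
  planted <- attr(traj, "planted")
  expect_equal(eigenvalues(sub)[1], 0.02 + 0.005^2, tolerance = 0.05)
  expect_equal(eigenvalues(sub)[2], 0.008 + 0.005^2, tolerance = 0.05)
  expect_gt(abs(sum(eigenvectors(sub)[, 1] * planted$directions[, 1])), 0.98)
  expect_gt(abs(sum(eigenvectors(sub)[, 2] * planted$directions[, 2])), 0.98)
})

test_that("projection variances equal eigenvalues; projections are centered", {
  traj <- genPlantedTrajectory(n_atoms = 8, n_frames = 600,
                               mode_variances = c(0.01, 0.004),
                               noise_sd = 0.002, seed = 33)
  sub <- fitAndCovariance(traj)
  proj <- projectTrajectory(traj, sub, 1:4)
  T_ <- nrow(proj)
  for (k in 1:4) {
    popVar <- sum((proj[, k] - mean(proj[, k]))^2) / T_
    expect_equal(popVar, eigenvalues(sub)[k], tolerance = 1e-8)
    expect_lt(abs(mean(proj[, k])), 1e-10)
  }
})

test_that("a second trajectory cross-projects into a reference subspace", {
  trajA <- genPlantedTrajectory(n_atoms = 10, n_frames = 300,
                                mode_variances = 0.01, seed = 34)
  trajB <- genPlantedTrajectory(n_atoms = 10, n_frames = 120,
                                mode_variances = 0.01, seed = 35)
  sub <- fitAndCovariance(trajA)
  proj <- projectTrajectory(trajB, sub, 1:2)
  expect_equal(dim(proj), c(120L, 2L))
  expect_error(projectTrajectory(trajB, sub, 31L), "out of range")
})

test_that("per-atom eigenvector components localize planted motion", {
  # only atoms 5-8 move: plant an internal (rigid-body-free) mode
  # supported on their coordinates, built as a null-space vector of the
  # rigid constraints restricted to those atoms
  n <- 12
  set.seed(360)
  base <- matrix(rnorm(3 * n), n, 3)
  support <- as.vector(vapply(5:8, function(a)
    (3 * (a - 1) + 1):(3 * a), integer(3)))
  rigid <- PMMpKa:::.rigidBodyBasis(base)
  M <- rigid[support, , drop = FALSE]       # 12 x 6 constraint block
  nullsp <- svd(M, nu = 12)$u[, (qr(M)$rank + 1):12, drop = FALSE]
  dir_ <- numeric(3 * n)
  dir_[support] <- nullsp %*% rnorm(ncol(nullsp))
  traj <- genPlantedTrajectory(n_atoms = n, n_frames = 3000,
                               mode_directions = matrix(dir_, ncol = 1),
                               mode_variances = 0.02, noise_sd = 0.001,
                               base_structure = base,
                               seed = 36)
  sub <- fitAndCovariance(traj)
  comp <- eigenvectorComponentsPerAtom(sub, 1)
  expect_length(comp, n)
  expect_equal(sum(comp^2), 1, tolerance = 1e-10)
  expect_gt(sum(comp[5:8]^2), 0.95)
})

test_that("eigenvalues are invariant under per-frame rigid-body motion", {
  plain <- genPlantedTrajectory(n_atoms = 10, n_frames = 800,
                                mode_variances = 0.01, noise_sd = 0.005,
                                rigid_body = FALSE, seed = 37)
  moved <- genPlantedTrajectory(n_atoms = 10, n_frames = 800,
                                mode_variances = 0.01, noise_sd = 0.005,
                                rigid_body = TRUE, seed = 37)
  evPlain <- eigenvalues(fitAndCovariance(plain))
  evMoved <- eigenvalues(fitAndCovariance(moved))
  expect_equal(evPlain, evMoved, tolerance = 1e-6)
})

test_that("mean dipole converts charge geometry to Debye", {
  # +1 e and -1 e separated by 0.1 nm, static: 0.1 e nm = 4.803 D
  coords <- array(0, c(2, 2, 3))
  coords[, 2, 1] <- 0.1
  traj <- CoordinateTrajectory(coords)
  expect_equal(meanDipole(traj, c(-1, 1)), 4.80321, tolerance = 1e-4)
  expect_equal(meanDipole(traj, c(0, 0)), 0)
  # doubling the separation doubles the dipole
  coords2 <- coords; coords2[, 2, 1] <- 0.2
  expect_equal(meanDipole(CoordinateTrajectory(coords2), c(-1, 1)),
               2 * meanDipole(traj, c(-1, 1)), tolerance = 1e-10)
})

test_that("residue distances average selection centroids over frames", {
  coords <- array(0, c(2, 2, 3))
  coords[1, 2, 1] <- 0.8
  coords[2, 2, 1] <- 1.2
  traj <- CoordinateTrajectory(coords, atomLabels = c("CYS32:CA", "CYS35:CA"))
  expect_equal(residueDistance(traj, 1, 2), 1.0, tolerance = 1e-12)
  expect_equal(residueDistance(traj, "CYS32", "CYS35"), 1.0,
               tolerance = 1e-12)
  expect_equal(residueDistance(traj, 1, 1), 0)
  expect_error(residueDistance(traj, "CYS99", 2), "empty")
  # static frames 1 nm apart
  coordsS <- array(0, c(3, 2, 3)); coordsS[, 2, 2] <- 1
  expect_equal(residueDistance(CoordinateTrajectory(coordsS), 1, 2), 1)
})

test_that("Pearson correlation matches published scan columns and edge identities", {
  dipoles <- c(311.93, 332.23, 387.08, 403.23, 470.80, 427.02, 479.36)
  dA <- c(1147.9, 1128.5, 1101.2, 1089.8, 1064.7, 1070.4, 1053.8)
  expect_equal(round(pearsonCorrelation(dipoles, dA), 3), -0.985)
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonCorrelation(x, x), 1.0)
  expect_equal(pearsonCorrelation(x, -x), -1.0)
  expect_error(pearsonCorrelation(x, rep(1, 4)), "zero variance")
  expect_error(pearsonCorrelation(x, x[1:3]), "equal-length")
})

test_that("PCA is invariant under a global rigid transformation of all frames", {
  traj <- genPlantedTrajectory(n_atoms = 9, n_frames = 400,
                               mode_variances = 0.01, noise_sd = 0.003,
                               seed = 38)
  coords <- coordinates(traj)
  set.seed(39)
  th <- runif(1, 0, pi)
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- rnorm(3)
  moved <- coords
  for (t in seq_len(dim(coords)[1]))
    moved[t, , ] <- sweep(coords[t, , ] %*% t(R), 2, -shift)
  ev1 <- eigenvalues(fitAndCovariance(traj))
  ev2 <- eigenvalues(fitAndCovariance(CoordinateTrajectory(moved)))
  expect_equal(ev1, ev2, tolerance = 1e-6)
})

test_that("XYZ trajectories round-trip", {
  traj <- genPlantedTrajectory(n_atoms = 5, n_frames = 4,
                               mode_variances = 0.01, seed = 40)
  f <- tempfile(fileext = ".xyz")
  writeTrajectoryXYZ(traj, f)
  back <- readTrajectoryXYZ(f)
  expect_equal(coordinates(back), coordinates(traj), tolerance = 1e-7)
  expect_identical(atomLabels(back), atomLabels(traj))
})
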