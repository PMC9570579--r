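# Independent oracle: builds the perturbed matrix element-by-element from
# the defining formulas and diagonalizes with a QR-iteration-free route
# (base eigen on the explicitly assembled matrix), kept separate from the
# package's vectorized construction.
oracleGroundEnergy <- function(qc, frame) {
  ns <- nStates(qc)
  H <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    H[i, i] <- stateEnergies(qc)[i]
    for (N in seq_len(nAtoms(qc)))
      H[i, i] <- H[i, i] + stateCharges(qc)[i, N] * frame@potentials[N]
    for (j in seq_len(ns)) {
      if (i == j) next
      H[i, j] <- -sum(frame@fieldAtR0 * dipoleArray(qc)[i, j, ])
    }
  }
  min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
}

test_that("zero perturbation reproduces the unperturbed spectrum exactly", {
  qc <- protonated(genQuantumCenterPair(n_states = 5, n_atoms = 4, seed = 1))
  H <- buildHamiltonian(qc, zeroFrame(qc))
  expect_identical(H, diag(stateEnergies(qc)))
  res <- diagonalizePerturbed(H)
  expect_equal(res$eigenvalues, stateEnergies(qc))
})

test_that("uniform potential shifts every diagonal by the total charge", {
  pair <- genQuantumCenterPair(n_states = 3, n_atoms = 4, seed = 2)
  V0 <- 10
  # methanethiolate-like species: q_T = -1, each diagonal shifts by -10
  d <- deprotonated(pair)
  H <- buildHamiltonian(d, uniformPotentialFrame(d, V0))
  expect_equal(diag(H), stateEnergies(d) - V0, tolerance = 1e-10)
  # neutral species: no shift
  p <- protonated(pair)
  Hp <- buildHamiltonian(p, uniformPotentialFrame(p, V0))
  expect_equal(diag(Hp), stateEnergies(p), tolerance = 1e-10)
  # off-diagonals stay zero (no field)
  expect_equal(H - diag(diag(H)), matrix(0, 3, 3))
})

test_that("2-state toy matches the closed-form 2x2 eigenvalues", {
  qc <- toyTwoState(gap = 100, mu01 = c(0.1, 0, 0))
  fr <- PerturbationFrame(0, matrix(0, 1, 3), 0, c(50, 0, 0))
  H <- buildHamiltonian(qc, fr)
  expect_equal(H[1, 2], -5)  # -E.mu = -(50 * 0.1)
  res <- diagonalizePerturbed(H)
  closed <- c((100 - sqrt(100^2 + 4 * 25)) / 2,
              (100 + sqrt(100^2 + 4 * 25)) / 2)
  expect_equal(res$eigenvalues, closed, tolerance = 1e-10)
  expect_equal(res$ground_energy, -0.2493781, tolerance = 1e-6)
})

test_that("diagonal input yields identity eigenvectors and trace is conserved", {
  res <- diagonalizePerturbed(diag(c(1, 5, 9)))
  expect_equal(res$eigenvalues, c(1, 5, 9))
  expect_equal(res$eigenvectors, diag(3))
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(49), 7, 7); A <- (A + t(A)) / 2
    res <- diagonalizePerturbed(A)
    expect_equal(sum(res$eigenvalues), sum(diag(A)), tolerance = 1e-8)
    expect_equal(crossprod(res$eigenvectors), diag(7), tolerance = 1e-8)
    expect_false(is.unsorted(res$eigenvalues))
    # sign convention: largest-magnitude component positive
    for (k in 1:7) {
      v <- res$eigenvectors[, k]
      expect_gt(v[which.max(abs(v))], 0)
    }
  }
})

test_that("non-symmetric and mismatched inputs are rejected", {
  expect_error(diagonalizePerturbed(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
  qc <- protonated(genQuantumCenterPair(n_states = 2, n_atoms = 3, seed = 3))
  shortFrame <- PerturbationFrame(numeric(2), matrix(0, 2, 3), 0, numeric(3))
  expect_error(buildHamiltonian(qc, shortFrame), "atoms")
})

test_that("energy series matches the independent per-frame oracle over 100 frames", {
  pair <- genQuantumCenterPair(n_states = 4, n_atoms = 5, seed = 4)
  frames <- genFieldFrames(pair, 100, mean_potential = 2, sd_potential = 4,
                           sd_field = 15, seed = 5)
  series <- perturbationEnergySeries(pair, frames, "protonated")
  expect_equal(nFrames(series), 100L)
  oracle <- vapply(frames, function(fp)
    oracleGroundEnergy(deprotonated(pair), fp$deprotonated) -
      oracleGroundEnergy(protonated(pair), fp$protonated), numeric(1))
  expect_equal(energyValues(series), oracle, tolerance = 1e-10)
})

test_that("zero frames give the unperturbed gap; uniform potential shifts it by -V0", {
  pair <- genQuantumCenterPair(n_states = 3, n_atoms = 4, seed = 6)
  p <- protonated(pair); d <- deprotonated(pair)
  gap0 <- stateEnergies(d)[1] - stateEnergies(p)[1]
  zf <- list(protonated = zeroFrame(p), deprotonated = zeroFrame(d))
  s0 <- perturbationEnergySeries(pair, list(zf, zf), "protonated")
  expect_equal(energyValues(s0), rep(gap0, 2), tolerance = 1e-10)
  V0 <- 13
  uf <- list(protonated = uniformPotentialFrame(p, V0),
             deprotonated = uniformPotentialFrame(d, V0))
  sU <- perturbationEnergySeries(pair, list(uf), "protonated")
  # charge difference q_T(deprot) - q_T(prot) = -1
  expect_equal(energyValues(sU), gap0 - V0, tolerance = 1e-10)
})

test_that("a protonated frame missing the acidic-proton site is rejected", {
  pair <- genQuantumCenterPair(n_states = 2, n_atoms = 4, seed = 7)
  small <- zeroFrame(deprotonated(pair))  # 3 centers, not 4
  expect_error(
    perturbationEnergySeries(pair, list(list(protonated = small,
                                             deprotonated = small)),
                             "protonated"),
    "proton")
})

test_that("ground-state response is first order in the perturbation (Richardson)", {
  qc <- protonated(genQuantumCenterPair(n_states = 4, n_atoms = 4, seed = 8))
  set.seed(9)
  V <- rnorm(nAtoms(qc), sd = 3)
  E <- matrix(rnorm(3 * nAtoms(qc), sd = 10), nAtoms(qc), 3)
  e0 <- rnorm(3, sd = 10)
  scaled <- function(eps) PerturbationFrame(eps * V, eps * E, 0, eps * e0)
  g <- function(eps) groundStateEnergy(qc, scaled(eps))
  analytic <- sum(stateCharges(qc)[1, ] * V)  # P_00 of the perturbation
  eps <- 1e-3
  d1 <- (g(eps) - g(-eps)) / (2 * eps)
  d2 <- (g(eps / 2) - g(-eps / 2)) / eps
  richardson <- (4 * d2 - d1) / 3
  expect_equal(richardson, analytic, tolerance = 1e-6)
})

test_that("energy series CSV round-trips with its ensemble label", {
  s <- PerturbationEnergySeries("deprotonated", c(1.5, -2.25, 1e3, 0.125))
  f <- tempfile(fileext = ".csv")
  writeEnergySeries(s, f)
  back <- readEnergySeries(f)
  expect_identical(ensembleLabel(back), "deprotonated")
  expect_equal(energyValues(back), energyValues(s), tolerance = 1e-12)
})
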