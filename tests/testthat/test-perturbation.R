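f_coulomb <- PMM_CONSTANTS$coulomb

test_that("empty environment gives an all-zero frame", {
  qc <- protonated(genQuantumCenterPair(n_states = 2, n_atoms = 3, seed = 1))
  fr <- evaluateFrame(ChargeEnvironment(matrix(numeric(), 0, 3),
                                        numeric()), qc)
  expect_equal(fr@potentials, numeric(nAtoms(qc)))
  expect_equal(fr@fields, matrix(0, nAtoms(qc), 3))
  expect_equal(fr@potentialAtR0, 0)
  expect_equal(fr@fieldAtR0, c(0, 0, 0))
})

test_that("single unit charge at 1 nm reproduces the Coulomb constant", {
  # lone expansion center at the origin: put the QC atom and r0 there
  qc <- QuantumCenter("probe", 0L,
                      data.frame(label = "X", element = "C",
                                 is_acidic_proton = FALSE),
                      matrix(0, 1, 3), energies = 0,
                      charges = matrix(0, 1, 1),
                      dipoles = array(0, c(1, 1, 3)))
  env <- ChargeEnvironment(matrix(c(1, 0, 0), 1, 3), charges = 1)
  fr <- evaluateFrame(env, qc)
  expect_equal(fr@potentials[1], f_coulomb, tolerance = 1e-12)
  expect_equal(sqrt(sum(fr@fields[1, ]^2)), f_coulomb, tolerance = 1e-12)
  expect_equal(fr@fields[1, ], c(-f_coulomb, 0, 0), tolerance = 1e-12)
})

test_that("mirror-symmetric charges cancel the field and double the potential", {
  qc <- QuantumCenter("probe", 0L,
                      data.frame(label = "X", element = "C",
                                 is_acidic_proton = FALSE),
                      matrix(0, 1, 3), energies = 0,
                      charges = matrix(0, 1, 1),
                      dipoles = array(0, c(1, 1, 3)))
  env <- ChargeEnvironment(rbind(c(0.7, 0, 0), c(-0.7, 0, 0)),
                           charges = c(1, 1))
  fr <- evaluateFrame(env, qc)
  expect_lt(max(abs(fr@fields)), 1e-9)
  expect_equal(fr@potentials[1], 2 * f_coulomb / 0.7, tolerance = 1e-12)
})

test_that("frames are linear in the environment", {
  qc <- protonated(genQuantumCenterPair(n_states = 2, n_atoms = 4, seed = 2))
  for (seed in 1:3) {
    set.seed(seed)
    mkenv <- function(n) ChargeEnvironment(
      matrix(runif(3 * n, 1.5, 3) * sample(c(-1, 1), 3 * n, TRUE), n, 3),
      charges = rnorm(n))
    e1 <- mkenv(5); e2 <- mkenv(7)
    both <- ChargeEnvironment(rbind(e1@positions, e2@positions),
                              c(e1@charges, e2@charges))
    fa <- evaluateFrame(e1, qc); fb <- evaluateFrame(e2, qc)
    fu <- evaluateFrame(both, qc)
    expect_equal(fu@potentials, fa@potentials + fb@potentials,
                 tolerance = 1e-9)
    expect_equal(fu@fields, fa@fields + fb@fields, tolerance = 1e-9)
    expect_equal(fu@fieldAtR0, fa@fieldAtR0 + fb@fieldAtR0,
                 tolerance = 1e-9)
  }
})

test_that("minimum-image convention wraps charges into the nearest image", {
  qc <- QuantumCenter("probe", 0L,
                      data.frame(label = "X", element = "C",
                                 is_acidic_proton = FALSE),
                      matrix(0, 1, 3), energies = 0,
                      charges = matrix(0, 1, 1),
                      dipoles = array(0, c(1, 1, 3)))
  box <- c(4, 4, 4)
  # charge at x = 3.5 in a 4 nm box is 0.5 nm away through the boundary
  envFar <- ChargeEnvironment(matrix(c(3.5, 0, 0), 1, 3), 1, box = box)
  envNear <- ChargeEnvironment(matrix(c(-0.5, 0, 0), 1, 3), 1)
  expect_equal(evaluateFrame(envFar, qc)@potentials,
               evaluateFrame(envNear, qc)@potentials, tolerance = 1e-12)
})

test_that("coincident charge raises a singularity error naming the pair", {
  pair <- genQuantumCenterPair(n_states = 1, n_atoms = 2, seed = 3)
  qc <- protonated(pair)
  env <- ChargeEnvironment(atomPositions(qc)[1, , drop = FALSE], 1)
  expect_error(evaluateFrame(env, qc), "singularity")
})

test_that("exogenous field: zero field is the identity, inverse restores", {
  pair <- genQuantumCenterPair(n_states = 2, n_atoms = 4, seed = 4)
  qc <- protonated(pair)
  set.seed(5)
  env <- ChargeEnvironment(matrix(runif(15, 2, 4), 5, 3), rnorm(5))
  fr <- evaluateFrame(env, qc)
  fr0 <- applyExogenousField(fr, c(0, 0, 0), qc)
  expect_equal(fr0@potentials, fr@potentials)
  expect_equal(fr0@fields, fr@fields)
  ext <- c(0.03, -0.05, 0.08)
  back <- applyExogenousField(applyExogenousField(fr, ext, qc), -ext, qc)
  expect_equal(back@potentials, fr@potentials, tolerance = 1e-12)
  expect_equal(back@fields, fr@fields, tolerance = 1e-12)
  expect_equal(back@fieldAtR0, fr@fieldAtR0, tolerance = 1e-12)
})

test_that("0.06 V/nm along z shifts an atom 0.1 nm above r0 as the unit conversion predicts", {
  # single-atom species placed exactly 0.1 nm above its center of mass is
  # impossible (com = atom), so use a 2-atom species with equal masses and
  # check the relative-position formula directly
  pos <- rbind(c(0, 0, 0.2), c(0, 0, 0))  # com at (0,0,0.1) for equal masses
  qc <- QuantumCenter("probe2", 0L,
                      data.frame(label = c("H1", "H2"), element = c("H", "H"),
                                 is_acidic_proton = c(FALSE, FALSE)),
                      pos, energies = 0, charges = matrix(0, 1, 2),
                      dipoles = array(0, c(1, 1, 3)))
  fr <- zeroFrame(qc)
  out <- applyExogenousField(fr, c(0, 0, 0.06), qc)
  # atom 1 sits at r0 + (0,0,0.1): potential gains -E'.(R-r0)
  expect_equal(out@potentials[1], -0.06 * PMM_CONSTANTS$voltPerNm * 0.1,
               tolerance = 1e-10)      # -0.578912 kJ/(mol e)
  expect_equal(out@potentials[1], -0.5789118, tolerance = 1e-6)
  expect_equal(out@fields[1, 3], 0.06 * PMM_CONSTANTS$voltPerNm,
               tolerance = 1e-10)      # +5.789118 kJ/(mol e nm)
  # gauge: potential at r0 untouched
  expect_identical(out@potentialAtR0, fr@potentialAtR0)
})

test_that("frame tables round-trip through the tabular format", {
  pair <- genQuantumCenterPair(n_states = 2, n_atoms = 3, seed = 6)
  qc <- protonated(pair)
  frames <- lapply(genFieldFrames(pair, 4, sd_potential = 2, sd_field = 5,
                                  seed = 7), `[[`, "protonated")
  f <- tempfile(fileext = ".tsv")
  writeFrameTable(frames, qc, f)
  back <- readFrameTable(f)
  expect_length(back, 4L)
  for (t in seq_along(frames)) {
    expect_equal(back[[t]]@potentials, frames[[t]]@potentials,
                 tolerance = 1e-12)
    expect_equal(back[[t]]@fields, frames[[t]]@fields, tolerance = 1e-12)
    expect_equal(back[[t]]@fieldAtR0, frames[[t]]@fieldAtR0,
                 tolerance = 1e-12)
  }
})

test_that("XYZQ point-charge files round-trip", {
  env <- ChargeEnvironment(matrix(c(1.5, 0, 0, 0, 2.5, 0), 2, 3,
                                  byrow = TRUE), c(0.5, -1))
  f <- tempfile(fileext = ".xyzq")
  writeChargeEnvironment(env, f)
  back <- readChargeEnvironment(f)
  expect_equal(back@positions, env@positions, tolerance = 1e-12)
  expect_equal(back@charges, env@charges, tolerance = 1e-12)
})
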