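test_that("pair force follows the piecewise-linear branches", {
  p <- sim_params(Ka = 1.2)
  expect_equal(pair_force_magnitude(0.10, p), 0)
  expect_equal(pair_force_magnitude(0.42, p), 0)   # d0 + d1: already null
  expect_equal(pair_force_magnitude(0.60, p), 0)
  expect_equal(pair_force_magnitude(0.05, p), -2.5)      # Kr * (d - d0)
  expect_equal(pair_force_magnitude(0.26, p), 0.192)     # Ka * (d - d0)
  # continuity at d0 from both sides
  eps <- 1e-9
  expect_lt(abs(pair_force_magnitude(0.1 - eps, p)), 1e-6)
  expect_lt(abs(pair_force_magnitude(0.1 + eps, p)), 1e-6)
})

test_that("interaction energies match the depletion-work estimates", {
  p <- sim_params(Ka = 1.2)
  expect_equal(attraction_work(p), 1.2 * 0.32^2 / 2)
  expect_equal(attraction_work(p), 0.06144, tolerance = 1e-12)
  expect_equal(attraction_work(p) / KT_PNUM, 14.95, tolerance = 0.01)
  expect_equal(repulsion_work(p), 0.25)
  expect_equal(repulsion_work(p) / KT_PNUM, 60.8, tolerance = 0.01)
  expect_equal(attraction_work(sim_params(Ka = 0)), 0)
})

test_that("integrated attractive force equals the attraction work", {
  p <- sim_params(Ka = 0.7)
  w <- stats::integrate(function(d) pair_force_magnitude(d, p),
                        p$d0, p$d0 + p$d1, rel.tol = 1e-10)$value
  expect_equal(w, attraction_work(p), tolerance = 1e-6)
})

test_that("steric forces vanish at equilibrium spacing and attract beyond", {
  p <- sim_params(Ka = 1.2)
  s0 <- pair_state(dy = 0.1)
  F0 <- steric_forces(s0, p)
  expect_lt(max(abs(F0)), 1e-12)

  s1 <- pair_state(dy = 0.2)
  F1 <- steric_forces(s1, p)
  nv <- s1$fil_nv[1]
  f1 <- F1[seq_len(nv), ]
  f2 <- F1[nv + seq_len(nv), ]
  # attraction: filament 1 pulled toward +y, filament 2 toward -y
  expect_true(all(f1[, 2] > 0))
  expect_true(all(f2[, 2] < 0))
  # orthogonal to both axes (x) and Newton pairs
  expect_lt(max(abs(F1[, 1])), 1e-12)
  expect_equal(colSums(F1), c(0, 0, 0), tolerance = 1e-12)
})

test_that("momentum is conserved on crowded random states", {
  p <- sim_params(Ka = 1.2)
  for (sd in 1:5) {
    s <- random_state(15, seed = sd)
    Fm <- steric_forces(s, p)
    expect_equal(colSums(Fm), c(0, 0, 0), tolerance = 1e-10)
  }
})

test_that("grid-accelerated steric forces equal the all-pairs oracle", {
  p <- sim_params(Ka = 1.2)
  for (sd in 1:10) {
    s <- random_state(20, seed = 100 + sd)
    expect_lt(max(abs(steric_forces(s, p) - brute_steric(s, p))), 1e-9)
  }
})

test_that("steric contact exerts no force along the neighbour's axis", {
  # two antiparallel filaments at d0 crosslinked by one motor must be able
  # to slide axially with zero steric resistance
  p <- sim_params(Ka = 1.2)
  s <- pair_state(dy = 0.1, antiparallel = TRUE)
  s$m_fil <- rbind(c(1L, 2L)); s$m_abs <- rbind(c(2, 2))
  s$m_pos <- matrix(0, 1, 3)
  Fm <- steric_forces(s, p)
  expect_lt(max(abs(Fm[, 1])), 1e-12)  # both axes along x
})

test_that("bending forces have the worm-like-chain structure", {
  straight <- cbind(0:5, 0, 0)
  expect_equal(bending_forces(straight, 20), matrix(0, 6, 3))
  expect_equal(bending_forces(straight[1:2, ], 20), matrix(0, 2, 3))

  # circular arc: interior force magnitudes equal by symmetry
  n <- 12; R <- 5
  th <- seq(0, pi / 3, length.out = n)
  arc <- cbind(R * cos(th), R * sin(th), 0)
  Fb <- bending_forces(arc, 20)
  mags <- sqrt(rowSums(Fb^2))
  inner <- mags[3:(n - 2)]
  expect_lt(diff(range(inner)) / mean(inner), 1e-6)
  # zero net force and zero net torque
  expect_equal(colSums(Fb), c(0, 0, 0), tolerance = 1e-10)
  tq <- colSums(cbind(
    arc[, 2] * Fb[, 3] - arc[, 3] * Fb[, 2],
    arc[, 3] * Fb[, 1] - arc[, 1] * Fb[, 3],
    arc[, 1] * Fb[, 2] - arc[, 2] * Fb[, 1]))
  expect_equal(tq, c(0, 0, 0), tolerance = 1e-10)
})

test_that("a force-free straight filament is a fixed point without noise", {
  p <- sim_params(kT = 0, alpha = 0, Omega = 100, n_fil = 1)
  s <- mt_state(list(cbind(10 + 0:3, 5, 0.1)), c(40, 40, 0.2))
  r <- step_state(s, p, n_steps = 50, seed = 1)
  expect_equal(r$state$vert, s$vert, tolerance = 1e-14)
  expect_equal(r$state$t, 50 * p$dt)
})

test_that("vertex spacing is restored exactly after noisy steps", {
  p <- sim_params(alpha = 0, Omega = 100, n_fil = 1)
  s <- mt_state(list(cbind(10 + 0:3, 5, 0.1)), c(40, 40, 0.2))
  r <- step_state(s, p, n_steps = 400, seed = 7)
  v <- r$state$vert
  d <- sqrt(rowSums(diff(v)^2))
  seg <- r$state$fil_L / (r$state$fil_nv - 1)
  expect_lt(max(abs(d - seg)) / seg, 1e-6)
  expect_equal(r$state$fil_L, s$fil_L)   # inextensible
})

test_that("free-filament diffusion obeys the Einstein relation", {
  p <- sim_params(alpha = 0, Omega = 1e5, n_fil = 1)
  s <- mt_state(list(cbind(10 + 0:3, 5, 0.1)), c(40, 40, 0.2))
  nrep <- 150; nst <- 150
  set.seed(99)
  msd <- replicate(nrep, {
    r <- step_state(s, p, n_steps = nst, seed = sample.int(1e6, 1))
    sum((colMeans(r$state$vert[, 1:2]) - colMeans(s$vert[, 1:2]))^2)
  })
  gamma <- p$drag_c * 3 * pi * p$eta * p$seg_len
  theory <- 4 * (p$kT / (4 * gamma)) * nst * p$dt   # 4 vertices share drag
  # chi-squared-ish sampling error: 3 relative SE of the mean of exponentials
  expect_lt(abs(mean(msd) - theory) / theory, 3 * sqrt(2 / nrep) + 0.1)
})
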