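test_that("walking follows the linear force-velocity law with clamping", {
  p <- sim_params()
  L <- 5; a <- 1
  expect_equal(walk_head(a, L, 0, p) - a, p$v_m * p$dt)            # unloaded
  expect_equal(walk_head(a, L, -p$f_stall, p), a)                  # stalled
  expect_equal(walk_head(a, L, -p$f_stall / 2, p) - a,
               p$v_m / 2 * p$dt)                                   # midpoint
  expect_equal(walk_head(a, L, +10 * p$f_stall, p) - a,
               p$v_m * p$dt)                                       # no super-speed
  expect_equal(walk_head(a, L, -3 * p$f_stall, p), a)              # no backstep
  # pinned at the plus end once reached
  expect_equal(walk_head(L - 1e-9, L, 0, p), L)
  expect_equal(walk_head(L, L, 0, p), L)
})

test_that("unbinding distinguishes side- and end-resident heads", {
  p <- sim_params()
  expect_equal(unbind_probability(2, 5, p), 1 - exp(-p$k_off_side * p$dt))
  expect_equal(unbind_probability(5, 5, p), 1 - exp(-p$k_off_end * p$dt))
  p0 <- sim_params(k_off_side = 0)
  set.seed(1)
  expect_false(any(attempt_unbind(rep(2, 1e4), 5, p0)))
})

test_that("end dwell times are exponential with mean 1/k_off_end", {
  p <- sim_params(dt = 0.01)            # rate 0.2/s
  dw <- sample_end_dwell(1e4, p, seed = 42)
  se <- stats::sd(dw) / sqrt(length(dw))
  expect_lt(abs(mean(dw) - 5), 3 * se + p$dt)
  # exponential shape: sd ~ mean for an exponential
  expect_equal(stats::sd(dw) / mean(dw), 1, tolerance = 0.05)
})

test_that("binding happens at rate k_on within the capture radius", {
  p <- sim_params(dt = 0.01, k_on = 5)  # k_on * dt = 0.05
  s <- mt_state(list(cbind(2 + 0:4, 5, 0.1)), c(20, 20, 0.2))
  pos_in <- c(4.3, 5 + 0.03, 0.1)
  pos_out <- c(4.3, 5 + 0.2, 0.1)
  set.seed(3)
  n <- 1e4
  hits <- sum(replicate(n, attempt_bind(pos_in, s, p)$bound))
  p_exp <- 1 - exp(-0.05)
  expect_lt(abs(hits / n - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
  expect_false(attempt_bind(pos_out, s, p)$bound)
  # the partner's filament is excluded from the candidates
  set.seed(4)
  trials <- replicate(200, attempt_bind(pos_in, s, p, exclude_fil = 1L)$bound)
  expect_false(any(trials))
})

test_that("binding site is the nearest projection and abscissa is exact", {
  p <- sim_params(k_on = 1e6)  # certain binding
  s <- mt_state(list(cbind(2 + 0:4, 5, 0.1)), c(20, 20, 0.2))
  set.seed(5)
  b <- attempt_bind(c(4.3, 5.02, 0.1), s, p)
  expect_true(b$bound)
  expect_equal(b$fil, 1L)
  expect_equal(b$a, 2.3, tolerance = 1e-12)
})

test_that("crosslink forces are Hookean, axial-resolved and balanced", {
  p <- sim_params(k_link = 100)
  s <- pair_state(dy = 0.1, antiparallel = TRUE)
  s$m_fil <- rbind(c(1L, 2L))
  s$m_pos <- matrix(0, 1, 3)
  # coincident world positions -> zero force
  s$m_abs <- rbind(c(2, 2))
  lf0 <- link_forces(s, p)
  expect_equal(lf0$motors$extension, 0.1)  # only the dy offset remains
  # axial offset of 0.1 um at k=100 -> 10 pN along the connector
  s$m_abs <- rbind(c(2.05, 1.85))
  lf <- link_forces(s, p)
  # head positions: x offset 0.1 (2.05 + 4 - 1.85 - 4 ... antiparallel)
  expect_equal(lf$motors$extension, sqrt(0.1^2 + 0.1^2), tolerance = 1e-12)
  expect_equal(sqrt(lf$motors$fx^2 + lf$motors$fy^2 + lf$motors$fz^2),
               100 * lf$motors$extension, tolerance = 1e-12)
  expect_equal(colSums(lf$vertex_forces), c(0, 0, 0), tolerance = 1e-12)
})

test_that("free motors obey the diffusion law and respect the slab", {
  box <- c(20, 20, 0.2)
  p0 <- sim_params(D_motor = 0)
  pos <- c(5, 5, 0.1)
  expect_equal(diffuse_free(pos, p0, box), pos)
  p <- sim_params(D_motor = 10, dt = 0.001)
  set.seed(6)
  n <- 5000
  P <- matrix(rep(c(5, 5, 0.1), each = n), n, 3)
  steps <- 20
  Q <- P
  for (k in seq_len(steps)) Q <- diffuse_free(Q, p, box)
  # x,y unwrapped displacement beyond one box length never happens here
  dx <- Q[, 1] - P[, 1]; dy <- Q[, 2] - P[, 2]
  msd <- mean(dx^2 + dy^2)
  theory <- 4 * p$D_motor * steps * p$dt
  expect_lt(abs(msd - theory) / theory, 3 * sqrt(2 / n) + 0.02)
  expect_true(all(Q[, 3] >= 0 & Q[, 3] <= box[3]))
})

test_that("motor count is conserved and heads partition exactly", {
  p <- default_params("fig1_lowdens", Ka = 0, box = c(10, 10), T_end = 0)
  s <- nucleate_state(p, seed = 2)
  n0 <- nrow(s$m_fil)
  r <- step_state(s, p, n_steps = 2000, seed = 2)
  cs <- motor_census(r$state)
  expect_equal(sum(cs), n0)
  expect_true(cs[["double"]] > 0)   # crosslinks did form
  validate_state(r$state)
})

test_that("single-head occupancy approaches the two-state balance", {
  # a head glued next to a filament: per-step bind prob p_on, unbind p_off;
  # stationary occupancy p_on / (p_on + p_off) for the two-state chain
  p <- sim_params(dt = 0.01, k_on = 5, k_off_side = 1, k_off_end = 1)
  s <- mt_state(list(cbind(2 + 0:4, 5, 0.1)), c(20, 20, 0.2))
  pos <- c(4.3, 5.02, 0.1)
  set.seed(8)
  bound <- FALSE; a <- 0
  occ <- logical(2e4)
  for (k in seq_along(occ)) {
    if (bound) {
      if (attempt_unbind(a, s$fil_L[1], p)) bound <- FALSE
    } else {
      bb <- attempt_bind(pos, s, p)
      if (bb$bound) { bound <- TRUE; a <- bb$a }
    }
    occ[k] <- bound
  }
  p_on <- 1 - exp(-p$k_on * p$dt)
  p_off <- 1 - exp(-p$k_off_side * p$dt)
  target <- p_on / (p_on + p_off)
  # crude 3-sigma band with an effective sample size from the relaxation time
  n_eff <- length(occ) / (1 / (p_on + p_off))
  expect_lt(abs(mean(occ) - target), 3 * sqrt(target * (1 - target) / n_eff))
})

test_that("a single motor transports an antiparallel cargo at ~v_m", {
  # long filament immobilized; short cargo crosslinked by one motor whose
  # cargo head is pinned at the cargo plus end: transport at v_m,
  # minus-end leading
  long <- cbind(0:10, 5, 0.1)
  cargo <- rbind(c(4, 5.08, 0.1), c(3, 5.08, 0.1))  # plus end toward -x
  st <- mt_state(list(long, cargo), c(40, 40, 0.2),
                 m_fil = rbind(c(1L, 2L)), m_abs = rbind(c(3, 1)),
                 fixed = c(TRUE, FALSE))
  p <- sim_params(alpha = 0, Omega = 100, n_fil = 2, k_off_side = 0,
                  k_off_end = 0, k_on = 0, kT = 0)
  tt <- 20
  r <- step_state(st, p, n_steps = round(tt / p$dt), seed = 3)
  v2 <- filament_vertices(r$state, 2)
  v_eff <- (v2[1, 1] - 4) / tt
  expect_lt(abs(v_eff - p$v_m) / p$v_m, 0.1)
  # the walking head advanced along the long filament
  expect_gt(r$state$m_abs[1, 1], 3.5)
  # mobility sign convention: minus-end leading => positive
  expect_gt(mobility(st, r$state, tt), 0)
})
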