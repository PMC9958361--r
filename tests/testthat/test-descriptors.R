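make_oriented_state <- function(angles, box = c(10, 10, 0.2), L = 2,
                                flip = NULL) {
  n <- length(angles)
  u <- cbind(cos(angles), sin(angles), 0)
  if (!is.null(flip)) u <- u * flip
  ctr <- cbind(runif(n, 0.45 * box[1], 0.55 * box[1]),
               runif(n, 0.45 * box[2], 0.55 * box[2]), box[3] / 2)
  fil <- lapply(seq_len(n), function(i)
    rbind(ctr[i, ] - L / 2 * u[i, ], ctr[i, ] + L / 2 * u[i, ]))
  mt_state(fil, box)
}

test_that("nematic order is 1 for aligned sets regardless of polarity", {
  set.seed(11)
  s <- make_oriented_state(rep(0.3, 40))
  expect_equal(nematic_order(s), 1, tolerance = 1e-12)
  s2 <- make_oriented_state(rep(0.3, 40), flip = rep(c(1, -1), 20))
  expect_equal(nematic_order(s2), 1, tolerance = 1e-12)
  # half +x / half -x
  s3 <- make_oriented_state(rep(0, 40), flip = rep(c(1, -1), 20))
  expect_equal(nematic_order(s3), 1, tolerance = 1e-12)
})

test_that("nematic order vanishes for balanced orthogonal populations", {
  set.seed(12)
  s <- make_oriented_state(rep(c(0, pi / 2), 20))
  expect_lt(nematic_order(s), 1e-12)
})

test_that("a large isotropic set has order near zero", {
  set.seed(13)
  fx <- make_fixture(fixture_spec("random_field", n = 1e5, L = 2,
                                  box = c(10, 10, 0.2), seed = 13))
  expect_lt(nematic_order(fx), 0.02)
})

test_that("nematic order is invariant to rotation and polarity flips", {
  set.seed(14)
  angles <- runif(30, 0, 2 * pi)
  s <- make_oriented_state(angles)
  S0 <- nematic_order(s)
  for (phi in c(0.7, 2.1)) {
    expect_equal(nematic_order(make_oriented_state(angles + phi)), S0,
                 tolerance = 1e-9)
  }
  flip <- sample(c(1, -1), 30, replace = TRUE)
  expect_equal(nematic_order(make_oriented_state(angles, flip = flip)), S0,
               tolerance = 1e-9)
})

test_that("link classification follows the angle bins and end override", {
  L <- 4
  mk <- function(theta, a1 = 2, a2 = 2) {
    u <- c(cos(theta), sin(theta), 0)
    f1 <- rbind(c(4, 5, 0.1), c(4 + L, 5, 0.1))
    f2 <- rbind(c(6, 5, 0.1) - L / 2 * u, c(6, 5, 0.1) + L / 2 * u)
    mt_state(list(f1, f2), c(20, 20, 0.2),
             m_fil = rbind(c(1L, 2L)), m_abs = rbind(c(a1, a2)))
  }
  get_class <- function(s) classify_links(s)$records$class
  expect_equal(get_class(mk(30 * pi / 180)), "P")
  expect_equal(get_class(mk(90 * pi / 180)), "X")
  expect_equal(get_class(mk(150 * pi / 180)), "AP")
  # bin boundaries: 60 and 120 degrees belong to X
  expect_equal(get_class(mk(60 * pi / 180)), "X")
  expect_equal(get_class(mk(120 * pi / 180)), "X")
  # plus-end proximity overrides the angle class
  expect_equal(get_class(mk(150 * pi / 180, a1 = L - 0.005)), "End")
  # but minus-end proximity does not
  expect_equal(get_class(mk(150 * pi / 180, a1 = 0.005)), "AP")
})

test_that("link fractions use the two stated normalizations", {
  # 2 End + 2 P + 1 AP + 1 X
  L <- 4
  f <- lapply(0:3, function(k) {
    th <- c(0, 0, pi, pi / 2)[k + 1]
    u <- c(cos(th), sin(th), 0)
    ctr <- c(6 + 2 * k, 10, 0.1)
    rbind(ctr - L / 2 * u, ctr + L / 2 * u)
  })
  base <- rbind(c(4, 9.9, 0.1), c(20, 9.9, 0.1))  # long partner filament
  s <- mt_state(c(list(base), f), c(40, 40, 0.2),
                m_fil = cbind(1L, 2:5)[c(1, 1, 2, 3, 4, 2), ],
                m_abs = rbind(c(2, L), c(6, L),      # End x2
                              c(4, 2), c(8, 2),     # P x2 (theta = 0)
                              c(10, 2),             # AP (theta = 180)
                              c(12, 2))[c(1, 2, 3, 4, 5, 6), ])
  cl <- classify_links(s)
  expect_equal(sort(cl$records$class), sort(c("End", "End", "P", "P", "AP", "X")))
  fr <- cl$fractions
  expect_equal(unname(fr["fEnd"]), 2 / 6)
  expect_equal(unname(fr["fP"]), 2 / 4)
  expect_equal(unname(fr["fAP"]), 1 / 4)
  expect_equal(unname(fr["fX"]), 1 / 4)
})

test_that("every doubly bound motor lands in exactly one class", {
  p <- sim_params()
  for (sd in 1:3) {
    s <- random_state(15, seed = 300 + sd)
    nm <- 30
    set.seed(sd)
    f1 <- sample(15, nm, replace = TRUE)
    f2 <- ((f1 + sample(13, nm, replace = TRUE) - 1) %% 15) + 1
    s$m_fil <- cbind(as.integer(f1), as.integer(f2))
    s$m_abs <- cbind(runif(nm) * s$fil_L[f1], runif(nm) * s$fil_L[f2])
    s$m_pos <- matrix(0, nm, 3)
    cl <- classify_links(s)
    expect_equal(nrow(cl$records), nm)
    expect_true(all(cl$records$class %in% c("P", "AP", "X", "End")))
  }
})

test_that("mobility measures signed axial minus-end translation", {
  fil <- rbind(c(5, 5, 0.1), c(7, 5, 0.1))  # minus at x=5, plus at x=7
  # minus-end-first translation (toward -x): positive mobility
  tr <- rigid_translation_traj(fil, c(-0.01, 0, 0), delta_t = 200)
  expect_equal(mobility(tr[[1]], tr[[2]], 200), +0.01)
  # plus-end-first translation: negative
  tr2 <- rigid_translation_traj(fil, c(+0.01, 0, 0), delta_t = 200)
  expect_equal(mobility(tr2[[1]], tr2[[2]], 200), -0.01)
  # orthogonal translation and the static case project to zero
  tr3 <- rigid_translation_traj(fil, c(0, 0.02, 0), delta_t = 200)
  expect_equal(mobility(tr3[[1]], tr3[[2]], 200), 0)
  tr4 <- rigid_translation_traj(fil, c(0, 0, 0), delta_t = 200)
  expect_equal(mobility(tr4[[1]], tr4[[2]], 200), 0)
})

test_that("pure diffusion averages to zero mobility at large delta-t", {
  p <- sim_params(alpha = 0, Omega = 1e5, n_fil = 1)
  s <- mt_state(list(cbind(10 + 0:2, 10, 0.1)), c(40, 40, 0.2))
  set.seed(21)
  vs <- replicate(60, {
    r <- step_state(s, p, n_steps = 2000, seed = sample.int(1e6, 1))
    mobility(s, r$state, 2000 * p$dt)
  })
  expect_lt(abs(mean(vs)), 3 * stats::sd(vs) / sqrt(length(vs)))
})

test_that("largest cluster fraction matches explicit component search", {
  mk_graph_state <- function(n, edges) {
    fil <- lapply(seq_len(n), function(i) cbind(c(i, i + 1), 2 * i, 0.1))
    s <- mt_state(fil, c(500, 500, 0.2))
    if (nrow(edges)) {
      s$m_fil <- matrix(as.integer(edges), ncol = 2)
      s$m_abs <- matrix(0.5, nrow(edges), 2)
      s$m_pos <- matrix(0, nrow(edges), 3)
    }
    s
  }
  expect_equal(largest_cluster_fraction(mk_graph_state(10, matrix(0, 0, 2))),
               0.1)
  chain <- cbind(1:9, 2:10)
  expect_equal(largest_cluster_fraction(mk_graph_state(10, chain)), 1)
  tri2 <- rbind(c(1, 2), c(2, 3), c(3, 1), c(4, 5), c(5, 6), c(6, 4))
  expect_equal(largest_cluster_fraction(mk_graph_state(6, tri2)), 0.5)
  set.seed(30)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    m <- sample(0:(2 * n), 1)
    edges <- if (m) cbind(sample(n, m, TRUE), sample(n, m, TRUE)) else
      matrix(0, 0, 2)
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    s <- mk_graph_state(n, edges)
    expect_equal(largest_cluster_fraction(s),
                 brute_largest_component(n, edges))
  }
})

test_that("descriptor vectors summarize archetype fixtures correctly", {
  box <- c(10, 10, 0.2)
  d_aster <- descriptor_vector(fixture_trajectory(
    make_fixture(fixture_spec("aster", n = 50, L = 2.5, box = box))))
  expect_equal(unname(d_aster["fEnd"]), 1)
  expect_lt(d_aster["S"], 0.2)
  expect_equal(unname(d_aster["cluster_frac"]), 1)

  d_par <- descriptor_vector(fixture_trajectory(
    make_fixture(fixture_spec("parallel_bundle", n = 20, L = 2.5, box = box))))
  expect_equal(unname(d_par["S"]), 1)
  expect_equal(unname(d_par["fP"]), 1)
  expect_equal(unname(d_par["mobility"]), 0)

  d_ap <- descriptor_vector(fixture_trajectory(
    make_fixture(fixture_spec("antiparallel_bundle", n = 20, L = 2.5,
                              box = box))))
  expect_equal(unname(d_ap["S"]), 1)
  expect_equal(unname(d_ap["fAP"]), 1)
  expect_gt(d_ap["mobility"], 0.005)
})

test_that("descriptor extraction demands the mobility frame pair", {
  fx <- make_fixture(fixture_spec("parallel_bundle", n = 10, L = 2.5,
                                  box = c(10, 10, 0.2)))
  tr <- fixture_trajectory(fx, delta_t = 200)
  expect_error(descriptor_vector(structure(list(tr[[2]]), class = "mt_traj"),
                                 delta_t = 200), "frame")
})
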