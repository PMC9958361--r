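# Independent brute-force oracles and small state generators used across
# the suite. These deliberately re-derive the physics from the written
# contracts (all-pairs loops, explicit component search) rather than
# calling the package's accelerated paths.

# brute-force all-pairs vertex-to-segment steric force field
brute_steric <- function(state, params) {
  Fv <- matrix(0, nrow(state$vert), 3)
  off <- filament_offsets(state)
  rng <- params$d0 + params$d1
  nf <- length(state$fil_nv)
  for (i in seq_len(nf)) {
    vi_rows <- (off[i] + 1):(off[i] + state$fil_nv[i])
    for (vi in seq_len(state$fil_nv[i])) {
      P <- state$vert[off[i] + vi, ]
      for (j in seq_len(nf)) {
        nvj <- state$fil_nv[j]
        for (k in seq_len(nvj - 1)) {
          if (j == i && k >= vi - 3 && k <= vi + 2) next
          A0 <- state$vert[off[j] + k, ]
          B0 <- state$vert[off[j] + k + 1, ]
          A <- P + min_image(P, A0, state$box)
          e <- B0 - A0
          tt <- sum((P - A) * e) / sum(e^2)
          if (tt >= 1) { if (k != nvj - 1) next else tt <- 1 }
          if (tt < 0) tt <- 0
          Q <- A + tt * e
          d <- sqrt(sum((P - Q)^2))
          if (d >= rng || d < 1e-9) next
          Fm <- if (d <= params$d0) params$Kr * (d - params$d0)
                else params$Ka * (d - params$d0)
          if (Fm == 0) next
          nh <- (P - Q) / d
          f <- -0.5 * Fm
          Fv[off[i] + vi, ] <- Fv[off[i] + vi, ] + f * nh
          Fv[off[j] + k, ] <- Fv[off[j] + k, ] - f * nh * (1 - tt)
          Fv[off[j] + k + 1, ] <- Fv[off[j] + k + 1, ] - f * nh * tt
        }
      }
    }
  }
  Fv
}

# explicit breadth-first component search on an adjacency list
brute_largest_component <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- rep(FALSE, n)
  best <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; size <- size + 1
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    best <- max(best, size)
  }
  best / n
}

# random multi-filament state (straight filaments, random lengths)
random_state <- function(n_fil = 20, box = c(12, 12, 0.2), seed = 1,
                         Lmin = 1, Lmax = 3) {
  set.seed(seed)
  fil <- lapply(seq_len(n_fil), function(i) {
    L <- runif(1, Lmin, Lmax)
    nv <- max(2, ceiling(L / 1.5) + 1)
    th <- runif(1, 0, 2 * pi)
    u <- c(cos(th), sin(th), 0)
    p0 <- c(runif(1, 0, box[1]), runif(1, 0, box[2]),
            runif(1, 0.02, box[3] - 0.02))
    t(sapply(seq_len(nv) - 1, function(k) p0 + k * (L / (nv - 1)) * u))
  })
  mt_state(fil, box)
}

# simple two-filament state at given spacing/orientation
pair_state <- function(dy = 0.1, antiparallel = FALSE, L = 4,
                       box = c(20, 20, 0.2)) {
  nv <- ceiling(L / 1.5) + 1
  sp <- L / (nv - 1)
  f1 <- cbind(8 + (0:(nv - 1)) * sp, 10, 0.1)
  f2 <- if (antiparallel) cbind(8 + L - (0:(nv - 1)) * sp, 10 + dy, 0.1)
        else cbind(8 + (0:(nv - 1)) * sp, 10 + dy, 0.1)
  mt_state(list(f1, f2), box)
}

expect_state_label <- function(truth) {
  switch(truth,
         antiparallel_bundle = "extensile_bundle",
         isotropic_mesh = "gliding_mesh",
         truth)
}
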