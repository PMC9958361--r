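# internal fast constructor (no validation loop; used for large fixtures)
new_state <- function(vert, nv, L, box, m_fil = NULL, m_abs = NULL,
                      m_pos = NULL, t = 0, fixed = NULL) {
  nm <- if (is.null(m_fil)) 0L else nrow(m_fil)
  if (nm == 0L) {
    m_fil <- matrix(integer(0), 0, 2)
    m_abs <- matrix(numeric(0), 0, 2)
    m_pos <- matrix(numeric(0), 0, 3)
  } else {
    m_fil <- matrix(as.integer(m_fil), nm, 2)
    m_abs <- matrix(as.numeric(m_abs), nm, 2)
    if (is.null(m_pos)) m_pos <- matrix(0, nm, 3)
  }
  if (is.null(fixed)) fixed <- rep(FALSE, length(nv))
  structure(list(t = t, box = as.numeric(box)[1:3], fil_nv = as.integer(nv),
                 fil_L = as.numeric(L), fil_fixed = fixed, vert = vert,
                 m_fil = m_fil, m_abs = m_abs, m_pos = m_pos,
                 total_polymer = sum(L)),
            class = "mt_state")
}

# vectorized straight-filament builder: minus ends M, unit directions U
straight_filaments <- function(M, U, L, spacing = 1.0) {
  n <- nrow(M)
  nv <- max(2L, as.integer(ceiling(L / (1.5 * spacing))) + 1L)
  sp <- L / (nv - 1)
  idx <- rep(seq_len(n), each = nv)
  frac <- rep(seq_len(nv) - 1L, n) * sp
  list(vert = M[idx, , drop = FALSE] + frac * U[idx, , drop = FALSE],
       nv = rep(nv, n), L = rep(L, n))
}

#' Specification of a synthetic network fixture
#'
#' Fixtures are configurations with analytically known descriptor values:
#' `aster` (filaments radiating from a focus, minus ends out, motors doubly
#' bound within the end radius of the plus ends), `parallel_bundle`
#' (co-oriented stacked filaments, motors mid-filament),
#' `antiparallel_bundle` (alternating polarity, motors mid-filament, an
#' optional prescribed minus-end-leading sliding speed),
#' `isotropic_mesh` (uniform random filaments with motors at geometric
#' crossing points) and `random_field` (uniform random filaments, no
#' motors). Motors are placed as already-doubly-bound records so descriptor
#' tests are decoupled from the binding kinetics.
#'
#' @param archetype one of the five archetypes above
#' @param n number of filaments
#' @param L filament length (um)
#' @param box `c(Lx, Ly, Lz)` (um)
#' @param pos_jitter positional noise amplitude (um)
#' @param angle_jitter orientation noise amplitude (rad)
#' @param n_motors number of crosslinking motors (default depends on the
#'   archetype)
#' @param slide_speed prescribed minus-end-leading sliding speed of the
#'   antiparallel bundle (um/s)
#' @param seed RNG seed
#' @return an object of class `mt_fixture_spec`
#' @export
fixture_spec <- function(archetype = c("aster", "parallel_bundle",
                                       "antiparallel_bundle",
                                       "isotropic_mesh", "random_field"),
                         n = 50, L = 2.5, box = c(40, 40, 0.2),
                         pos_jitter = 0, angle_jitter = 0, n_motors = NULL,
                         slide_speed = 0.02, seed = 1L) {
  archetype <- match.arg(archetype)
  if (is.null(n_motors))
    n_motors <- switch(archetype, isotropic_mesh = 2L * n, random_field = 0L, n)
  structure(list(archetype = archetype, n = as.integer(n), L = L, box = box,
                 pos_jitter = pos_jitter, angle_jitter = angle_jitter,
                 n_motors = as.integer(n_motors), slide_speed = slide_speed,
                 seed = as.integer(seed)),
            class = "mt_fixture_spec")
}

#' Build a synthetic network configuration from a fixture specification
#'
#' Deterministic for a given seed. The returned state carries a
#' `velocity` attribute (n x 3, um/s) holding any prescribed rigid
#' filament motion (used by [fixture_trajectory()] to fabricate a second
#' frame for the mobility descriptor) and a `truth` attribute with the
#' archetype's ground-truth state label.
#'
#' @param spec an `mt_fixture_spec`
#' @return an `mt_state`
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "mt_fixture_spec"))
  # random fields carry no interactions or motors: they are measurement
  # fixtures (orientation statistics) and may exceed physical packing
  if (spec$archetype != "random_field" &&
      spec$n * spec$L > prod(spec$box) / 6.25e-4)
    stop("overfilled box: requested polymer exceeds the packing limit")
  with_seed(spec$seed, {
    n <- spec$n; L <- spec$L; box <- spec$box
    ctr <- c(box[1] / 2, box[2] / 2, box[3] / 2)
    jp <- function(M) M + cbind(stats::rnorm(n, 0, spec$pos_jitter),
                                stats::rnorm(n, 0, spec$pos_jitter), 0)
    vel <- matrix(0, n, 3)
    m_fil <- NULL; m_abs <- NULL
    truth <- spec$archetype
    if (spec$archetype == "aster") {
      th <- 2 * pi * (seq_len(n) - 1) / n +
        stats::rnorm(n, 0, spec$angle_jitter)
      U <- cbind(cos(th), sin(th), 0)
      r0 <- 0.1
      # centred inside one 10 um analysis window so the radial arrangement
      # averages to zero order within that window
      actr <- c(min(5, box[1] / 2), min(5, box[2] / 2), box[3] / 2)
      minus <- jp(rep(1, n) %o% actr + (r0 + L) * U)
      fil <- straight_filaments(minus, -U, L)
      pair <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))[seq_len(min(spec$n_motors, n)), , drop = FALSE]
      m_fil <- pair
      m_abs <- matrix(L - 0.002, nrow(pair), 2)
    } else if (spec$archetype %in% c("parallel_bundle", "antiparallel_bundle")) {
      flip <- if (spec$archetype == "antiparallel_bundle")
        rep(c(1, -1), length.out = n) else rep(1, n)
      th <- stats::rnorm(n, 0, spec$angle_jitter)
      U <- cbind(flip * cos(th), flip * sin(th), 0)
      if (spec$archetype == "parallel_bundle") {
        # several disconnected co-oriented bundles: the parallel-bundle
        # state signature pairs high order with a small cluster size
        per <- 6L
        grp <- (seq_len(n) - 1L) %/% per
        ng <- max(grp) + 1L
        gy <- ctr[2] + (grp - (ng - 1) / 2) * min(2, (box[2] - 1) / max(1, ng))
        y0 <- gy + ((seq_len(n) - 1L) %% per - (per - 1) / 2) * 0.1
        minus <- jp(cbind(ctr[1] - flip * L / 2, y0, ctr[3]))
        fil <- straight_filaments(minus, U, L)
        same <- grp[-n] == grp[-1]
        pair <- cbind(which(same), which(same) + 1L)
        pair <- pair[seq_len(min(spec$n_motors, nrow(pair))), , drop = FALSE]
        m_fil <- pair
        m_abs <- matrix(L / 2, nrow(pair), 2)
        truth <- "parallel_bundle"
      } else {
        y0 <- ctr[2] + (seq_len(n) - (n + 1) / 2) * 0.1
        minus <- jp(cbind(ctr[1] - flip * L / 2, y0, ctr[3]))
        fil <- straight_filaments(minus, U, L)
        npairs <- min(spec$n_motors, n - 1)
        pair <- cbind(seq_len(npairs), seq_len(npairs) + 1L)
        m_fil <- pair
        m_abs <- matrix(L / 2, npairs, 2)
        vel <- -spec$slide_speed * U  # minus-end leading
        truth <- "extensile_bundle"
      }
    } else { # isotropic_mesh, random_field
      th <- stats::runif(n, 0, 2 * pi)
      U <- cbind(cos(th), sin(th), 0)
      P <- cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
                 ctr[3])
      minus <- P - L / 2 * U
      fil <- straight_filaments(minus, U, L)
      if (spec$archetype == "isotropic_mesh") {
        # a gliding mesh is percolated by definition: redraw filaments
        # that end up crossing nothing until the crossing graph connects
        # all of them (deterministic given the seed)
        for (iter in 1:50) {
          cross <- chord_crossings(P, U, L, box = box)
          comp <- rep(seq_len(n), 1)
          for (r in seq_len(nrow(cross))) {
            ci <- comp[cross[r, 1]]; cj <- comp[cross[r, 2]]
            if (ci != cj) comp[comp == cj] <- ci
          }
          big <- as.integer(names(which.max(table(comp))))
          lonely <- which(comp != big)
          if (!length(lonely)) break
          th2 <- stats::runif(length(lonely), 0, 2 * pi)
          U[lonely, ] <- cbind(cos(th2), sin(th2), 0)
          P[lonely, 1] <- stats::runif(length(lonely), 0, box[1])
          P[lonely, 2] <- stats::runif(length(lonely), 0, box[2])
        }
        minus <- P - L / 2 * U
        fil <- straight_filaments(minus, U, L)
        if (nrow(cross) > spec$n_motors) {
          # keep a spanning set of crossings so subsampling cannot break
          # the percolation, then fill up with random extras
          ord <- sample.int(nrow(cross))
          comp <- seq_len(n)
          keep <- logical(nrow(cross))
          for (r in ord) {
            ci <- comp[cross[r, 1]]; cj <- comp[cross[r, 2]]
            if (ci != cj) { keep[r] <- TRUE; comp[comp == cj] <- ci }
          }
          extra <- setdiff(ord, which(keep))
          n_extra <- max(0, spec$n_motors - sum(keep))
          keep[extra[seq_len(min(n_extra, length(extra)))]] <- TRUE
          cross <- cross[keep, , drop = FALSE]
        }
        m_fil <- cross[, 1:2, drop = FALSE]
        m_abs <- cross[, 3:4, drop = FALSE]
        truth <- "gliding_mesh"
      } else truth <- "random_field"
    }
    s <- new_state(fil$vert, fil$nv, fil$L, box, m_fil = m_fil, m_abs = m_abs)
    attr(s, "velocity") <- vel
    attr(s, "truth") <- truth
    if (spec$n <= 500) validate_state(s)
    s
  })
}

# geometric crossings of in-plane chords: centers P, directions U, length L;
# the x,y displacement between centers is taken under the minimum image so
# chords crossing through the periodic boundary are found too
chord_crossings <- function(P, U, L, box = NULL) {
  n <- nrow(P)
  out <- matrix(0, 0, 4)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- P[j, 1:2] - P[i, 1:2]
    if (!is.null(box)) d <- d - box[1:2] * round(d / box[1:2])
    det <- U[i, 1] * U[j, 2] - U[i, 2] * U[j, 1]
    if (abs(det) < 1e-9) next
    s <- (d[1] * U[j, 2] - d[2] * U[j, 1]) / det
    t <- (d[1] * U[i, 2] - d[2] * U[i, 1]) / det
    if (abs(s) <= L / 2 && abs(t) <= L / 2)
      out <- rbind(out, c(i, j, s + L / 2, t + L / 2))
  }
  out
}

#' Two-frame trajectory of a fixture with its prescribed rigid motion
#'
#' Fabricates the frame pair the mobility descriptor needs: the fixture at
#' time `t` and a copy rigidly translated by `velocity * delta_t` at
#' `t + delta_t`.
#'
#' @param state a fixture `mt_state` (with a `velocity` attribute)
#' @param delta_t frame interval (s)
#' @return an `mt_traj` with two frames
#' @export
fixture_trajectory <- function(state, delta_t = 200) {
  vel <- attr(state, "velocity")
  if (is.null(vel)) vel <- matrix(0, length(state$fil_nv), 3)
  s2 <- state
  idx <- rep(seq_along(state$fil_nv), state$fil_nv)
  s2$vert <- state$vert + vel[idx, , drop = FALSE] * delta_t
  s2$t <- state$t + delta_t
  structure(list(state, s2), class = "mt_traj")
}

#' Rigid-translation trajectory of a single filament
#'
#' Oracle fixture for the mobility sign convention: a filament translated
#' at constant velocity, sampled at regular intervals.
#'
#' @param filament nv x 3 vertex matrix (minus end first)
#' @param velocity 3-vector (um/s)
#' @param delta_t frame interval (s)
#' @param frames number of frames (>= 2)
#' @param box `c(Lx, Ly, Lz)`
#' @return an `mt_traj`
#' @export
rigid_translation_traj <- function(filament, velocity, delta_t = 200,
                                   frames = 2, box = c(40, 40, 0.2)) {
  sp <- sqrt(sum((filament[2, ] - filament[1, ])^2))
  L <- (nrow(filament) - 1) * sp
  fr <- lapply(seq_len(frames) - 1, function(k)
    new_state(filament + rep(1, nrow(filament)) %o% (velocity * k * delta_t),
              nrow(filament), L, box, t = k * delta_t))
  structure(fr, class = "mt_traj")
}

#' Synthetic descriptor sweep over a parameter grid
#'
#' Emulates a phase-space sweep: each grid point (density, L) is assigned
#' an archetype, its fixture descriptors are computed exactly, and
#' optional Gaussian noise of amplitude `noise_sd` is added to every
#' descriptor. Ground-truth labels are retained in the `truth` column.
#'
#' @param densities,Ls grid axes (um/um^2 and um)
#' @param archetype_map function(density, L) returning an archetype name;
#'   default [default_archetype_map()]
#' @param noise_sd Gaussian noise amplitude on all descriptors
#' @param n filaments per fixture
#' @param box fixture box
#' @param seed RNG seed
#' @return data frame (class `mt_sweep`): run_id, density, L, truth and the
#'   7 descriptor columns
#' @export
make_sweep <- function(densities = c(1.3, 2.5, 5, 7.5, 10),
                       Ls = c(2.5, 5, 7.5, 10, 15),
                       archetype_map = default_archetype_map,
                       noise_sd = 0, n = 40, box = c(10, 10, 0.2),
                       seed = 1L) {
  grid <- expand.grid(density = densities, L = Ls)
  archs <- c("aster", "parallel_bundle", "antiparallel_bundle",
             "isotropic_mesh", "random_field")
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    arch <- archetype_map(grid$density[r], grid$L[r])
    # one deterministic geometry per archetype; row-to-row variation comes
    # from the descriptor-space noise term
    spec <- fixture_spec(arch, n = n, L = min(grid$L[r], box[1] / 2.5),
                         box = box, seed = seed + match(arch, archs))
    fx <- make_fixture(spec)
    d <- descriptor_vector(fixture_trajectory(fx), window = 10)
    cbind(data.frame(run_id = r, density = grid$density[r], L = grid$L[r],
                     truth = attr(fx, "truth")), as.data.frame(t(d)))
  })
  out <- do.call(rbind, rows)
  if (noise_sd > 0) {
    # noise acts on the standardized scale: the descriptors mix units
    # (um/s against dimensionless fractions), so the amplitude is a
    # fraction of each descriptor's across-sweep standard deviation
    sc <- apply(out[DESCRIPTOR_COLS], 2, stats::sd)
    sc[sc == 0] <- 1
    out[DESCRIPTOR_COLS] <- with_seed(seed,
      out[DESCRIPTOR_COLS] +
        matrix(stats::rnorm(nrow(out) * 7, 0, noise_sd), nrow(out), 7,
               byrow = FALSE) * rep(sc, each = nrow(out)))
  }
  class(out) <- c("mt_sweep", "data.frame")
  out
}

#' Default archetype layout of the synthetic (density, length) phase grid
#'
#' Short filaments form asters; long filaments form parallel bundles at low
#' density, extensile bundles at intermediate density and a gliding mesh at
#' the highest densities.
#'
#' @param density total filament length per area (um/um^2)
#' @param L filament length (um)
#' @return archetype name
#' @export
default_archetype_map <- function(density, L) {
  if (L <= 2.5) "aster"
  else if (density <= 2.5) "parallel_bundle"
  else if (density < 10) "antiparallel_bundle"
  else "isotropic_mesh"
}
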