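#' Force-velocity law of a walking motor head
#'
#' A bound head advances toward the plus end with
#' `v = clamp(v_m (1 + f_axial / f_stall), 0, v_m)`: unloaded heads move at
#' `v_m`, a load of `-f_stall` stalls them, assisting loads do not speed
#' them up, and there is no backward stepping. The abscissa is clamped at
#' the filament length; a head that reaches the plus end stays pinned there
#' (end-resident) until it unbinds.
#'
#' @param a abscissa from the minus end (um)
#' @param L filament length (um)
#' @param f_axial signed axial load (pN), positive toward the plus end
#' @param params an `mt_params`
#' @return new abscissa (um)
#' @export
walk_head <- function(a, L, f_axial, params) {
  v <- params$v_m * (1 + f_axial / params$f_stall)
  v <- pmin(pmax(v, 0), params$v_m)
  pmin(a + v * params$dt, L)
}

#' Per-step unbinding probability of a bound head
#'
#' End-resident heads (abscissa exactly at the plus end after clamping)
#' detach at `k_off_end`, side-bound heads at `k_off_side`; the per-step
#' probability is `1 - exp(-rate dt)`.
#'
#' @param a abscissa (um)
#' @param L filament length (um)
#' @param params an `mt_params`
#' @return probability in `[0, 1]`
#' @export
unbind_probability <- function(a, L, params) {
  rate <- ifelse(a >= L - 1e-12, params$k_off_end, params$k_off_side)
  1 - exp(-rate * params$dt)
}

#' Stochastic unbinding of one bound head
#'
#' @inheritParams unbind_probability
#' @return `TRUE` if the head detaches this step
#' @export
attempt_unbind <- function(a, L, params) {
  stats::runif(length(a)) < unbind_probability(a, L, params)
}

#' Stochastic binding of a free head to a nearby filament
#'
#' The nearest point of any candidate filament (excluding the partner
#' head's filament) within the capture radius `r_bind` is the binding site;
#' the head binds there with probability `1 - exp(-k_on dt)`. With no
#' candidate in range the head stays free.
#'
#' @param pos 3-vector, world position of the free head (um)
#' @param state an `mt_state`
#' @param params an `mt_params`
#' @param exclude_fil filament index the partner head occupies (0 = none)
#' @return list `(bound, fil, a)`; `bound = FALSE` leaves `fil = 0`
#' @export
attempt_bind <- function(pos, state, params, exclude_fil = 0L) {
  best <- list(d2 = params$r_bind^2, fil = 0L, a = 0)
  for (i in seq_along(state$fil_nv)) {
    if (i == exclude_fil) next
    v <- filament_vertices(state, i)
    seg <- state$fil_L[i] / (state$fil_nv[i] - 1)
    for (k in seq_len(state$fil_nv[i] - 1)) {
      A <- pos + min_image(pos, v[k, ], state$box)
      e <- v[k + 1, ] - v[k, ]
      u <- sum((pos - A) * e) / sum(e^2)
      if (u >= 1) { if (k != state$fil_nv[i] - 1) next else u <- 1 }
      if (u < 0) u <- 0
      q <- A + u * e
      d2 <- sum((pos - q)^2)
      if (d2 < best$d2) best <- list(d2 = d2, fil = i, a = (k - 1 + u) * seg)
    }
  }
  if (best$fil > 0L && stats::runif(1) < 1 - exp(-params$k_on * params$dt))
    return(list(bound = TRUE, fil = best$fil, a = min(best$a, state$fil_L[best$fil])))
  list(bound = FALSE, fil = 0L, a = 0)
}

#' Hookean crosslink forces of all doubly bound motors
#'
#' Each doubly bound motor pulls its two attachment points together with
#' `f = k_link * (minimum-image separation)`; equal and opposite forces are
#' distributed onto the adjacent filament vertices by linear interpolation
#' of the abscissa, and the signed axial components (positive toward the
#' plus end) are what the walking law sees as load.
#'
#' @param state an `mt_state`
#' @param params an `mt_params`
#' @return list with `motors` (data frame: motor, force components on head
#'   1, axial loads `f_ax1`, `f_ax2`, extension) and `vertex_forces`
#'   (n_vertices x 3 matrix, pN)
#' @export
link_forces <- function(state, params) {
  F <- matrix(0, nrow(state$vert), 3)
  off <- filament_offsets(state)
  dbl <- which(state$m_fil[, 1] > 0 & state$m_fil[, 2] > 0)
  rows <- lapply(dbl, function(m) {
    i1 <- state$m_fil[m, 1]; i2 <- state$m_fil[m, 2]
    a1 <- state$m_abs[m, 1]; a2 <- state$m_abs[m, 2]
    p1 <- filament_point(state, i1, a1)
    p2 <- filament_point(state, i2, a2)
    dv <- min_image(p1, p2, state$box)
    Fv <- params$k_link * dv
    fax <- numeric(2)
    for (h in 1:2) {
      i <- if (h == 1) i1 else i2
      a <- if (h == 1) a1 else a2
      sgn <- if (h == 1) 1 else -1
      seg <- state$fil_L[i] / (state$fil_nv[i] - 1)
      k <- min(max(floor(a / seg), 0), state$fil_nv[i] - 2)
      u <- a / seg - k
      r <- off[i] + k + 1
      F[r, ] <<- F[r, ] + sgn * Fv * (1 - u)
      F[r + 1, ] <<- F[r + 1, ] + sgn * Fv * u
      fax[h] <- sgn * sum(Fv * filament_tangent(state, i, a))
    }
    c(m, Fv, fax, sqrt(sum(dv^2)))
  })
  mot <- if (length(rows)) {
    d <- as.data.frame(do.call(rbind, rows))
    names(d) <- c("motor", "fx", "fy", "fz", "f_ax1", "f_ax2", "extension")
    d
  } else {
    data.frame(motor = integer(0), fx = numeric(0), fy = numeric(0),
               fz = numeric(0), f_ax1 = numeric(0), f_ax2 = numeric(0),
               extension = numeric(0))
  }
  list(motors = mot, vertex_forces = F)
}

#' Brownian displacement of a fully detached motor
#'
#' @param pos 3-vector or n x 3 matrix of motor positions (um)
#' @param params an `mt_params`
#' @param box `c(Lx, Ly, Lz)`
#' @return updated positions; x,y wrapped, z reflected into `[0, Lz]`
#' @export
diffuse_free <- function(pos, params, box) {
  p <- if (is.matrix(pos)) pos else matrix(pos, 1, 3)
  step <- sqrt(2 * params$D_motor * params$dt)
  p <- p + matrix(stats::rnorm(length(p), 0, step), nrow(p), 3)
  p <- wrap_xy(p, box)
  z <- p[, 3]
  while (any(bad <- z < 0 | z > box[3]))
    z[bad] <- ifelse(z[bad] < 0, -z[bad], 2 * box[3] - z[bad])
  p[, 3] <- z
  if (is.matrix(pos)) p else p[1, ]
}

#' Sample end-residence dwell times with the discrete-time kinetic scheme
#'
#' Draws `n` dwell times of a plus-end-resident head by iterating the
#' per-step Bernoulli unbinding trial at probability
#' `1 - exp(-k_off_end dt)`; the expected mean is `1 / k_off_end` up to the
#' `O(dt)` discretization offset.
#'
#' @param n number of events
#' @param params an `mt_params` (uses `k_off_end` and `dt`)
#' @param seed RNG seed
#' @return numeric vector of dwell times (s)
#' @export
sample_end_dwell <- function(n, params, seed = params$seed) {
  p <- 1 - exp(-params$k_off_end * params$dt)
  cpp_dwell_steps(as.integer(n), p, as.integer(seed)) * params$dt
}

#' Head-occupancy bookkeeping of the motor population
#'
#' @param state an `mt_state`
#' @return named integer vector: `free`, `single`, `double` motor counts
#' @export
motor_census <- function(state) {
  nb <- rowSums(state$m_fil > 0)
  c(free = sum(nb == 0), single = sum(nb == 1), double = sum(nb == 2))
}
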