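#' Piecewise-linear steric/depletion pair force
#'
#' Signed force between a filament vertex and the nearest point on another
#' filament at separation `d`: `F(d) = k (d - d0)` with `k = Kr` (repulsive
#' branch) for `d <= d0`, `k = Ka` (attractive branch) for
#' `d0 < d <= d0 + d1`, and zero beyond. Negative values push the filaments
#' apart, positive values pull them together; both branches vanish at `d0`.
#'
#' @param d separation (um), scalar or vector, `d >= 0`
#' @param params an `mt_params`
#' @return signed force (pN), same length as `d`
#' @export
pair_force_magnitude <- function(d, params) {
  stopifnot(all(d >= 0))
  # the cutoff is compared with a small tolerance so that a literal
  # d0 + d1 (whose floating sum exceeds the decimal value) is "beyond"
  ifelse(d <= params$d0, params$Kr * (d - params$d0),
         ifelse(d < params$d0 + params$d1 - 1e-12,
                params$Ka * (d - params$d0), 0))
}

#' Maximum mechanical work of the attractive branch
#'
#' The work needed to separate two filaments from the equilibrium spacing
#' `d0` out of the attractive shell: `Ka * d1^2 / 2` (pN um).
#'
#' @param params an `mt_params`
#' @return energy (pN um)
#' @export
attraction_work <- function(params) params$Ka * params$d1^2 / 2

#' Maximum repulsive energy of the pair force
#'
#' Energy to bring two filaments from `d0` into full overlap:
#' `Kr * d0^2 / 2` (pN um).
#'
#' @param params an `mt_params`
#' @return energy (pN um)
#' @export
repulsion_work <- function(params) params$Kr * params$d0^2 / 2

#' Steric/depletion force field on all vertices
#'
#' Evaluates the pair force between every vertex and the segments of other
#' filaments (vertex-to-segment projection, minimum image, symmetric
#' double-counting halved, two-segment exclusion window on the same
#' filament) using a uniform neighbor grid. Forces are applied along the
#' contact normal in Newton's-third-law pairs, so they sum to zero.
#'
#' @param state an `mt_state`
#' @param params an `mt_params`
#' @return n_vertices x 3 matrix of forces (pN), rows ordered as
#'   `state$vert`
#' @export
steric_forces <- function(state, params) {
  cpp_steric_forces(engine_state(state), engine_params(state, params))
}

#' Bending elasticity forces of one filament
#'
#' Discrete worm-like-chain bending force: for each interior vertex the
#' second difference `b_j = v_{j-1} - 2 v_j + v_{j+1}` contributes the
#' stencil `(-k b, +2k b, -k b)` with `k = kappa / spacing^3`. The field
#' sums to zero force and zero torque; fewer than 3 vertices give a zero
#' field.
#'
#' @param vertices nv x 3 vertex matrix of one filament (equal spacing)
#' @param kappa bending rigidity (pN um^2)
#' @return nv x 3 force matrix (pN)
#' @export
bending_forces <- function(vertices, kappa) {
  nv <- nrow(vertices)
  spacing <- sqrt(sum((vertices[2, ] - vertices[1, ])^2))
  cpp_bending_forces(vertices, spacing, kappa)
}

#' Advance the simulation by explicit overdamped Langevin steps
#'
#' Each step evaluates bending, steric and motor-link forces, displaces
#' every vertex by `F dt / gamma` plus a Brownian kick of variance
#' `2 kT dt / gamma` (per-vertex drag `gamma = drag_c 3 pi eta seg_len`),
#' reflects z at the walls, restores equal vertex spacing by arc-length
#' re-projection, applies tubulin-limited plus-end growth, and runs the
#' motor kinetics (walk, unbind, bind, diffuse). A vertex displacement
#' exceeding half the segment length aborts with an unstable-timestep
#' error.
#'
#' @param state an `mt_state`
#' @param params an `mt_params`
#' @param n_steps number of time steps
#' @param seed RNG seed for this run segment
#' @param snapshot_steps integer step indices (1-based) at which full state
#'   snapshots are recorded
#' @return list with elements `state` (the advanced `mt_state`),
#'   `snapshots` (list of `mt_state`), `snapshot_steps` and `n_clamped`
#'   (count of displacement-limited vertex moves, a stiffness diagnostic)
#' @export
step_state <- function(state, params, n_steps = 1L, seed = params$seed,
                       snapshot_steps = integer(0)) {
  res <- cpp_run(engine_state(state), engine_params(state, params),
                 as.integer(n_steps), as.integer(seed),
                 as.integer(snapshot_steps))
  res
}

# engine adapters: ensure box/params agree and fields are complete
engine_state <- function(state) {
  stopifnot(inherits(state, "mt_state"))
  state
}

engine_params <- function(state, params) {
  p <- unclass(params)
  p$Lx <- state$box[1]; p$Ly <- state$box[2]; p$Lz <- state$box[3]
  p
}
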