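#' Per-motor table with head states and link forces
#'
#' One row per motor: head filament ids (0 = free), abscissae, the world
#' position of each head, and for doubly bound motors the Hookean link
#' extension and force magnitude.
#'
#' @param state an `mt_state`
#' @param params an `mt_params` (for `k_link`)
#' @return data frame: motor, fil1, a1, fil2, a2, x1..z2, extension,
#'   force (pN)
#' @export
motor_table <- function(state, params) {
  nm <- nrow(state$m_fil)
  if (nm == 0)
    return(data.frame(motor = integer(0), fil1 = integer(0), a1 = numeric(0),
                      fil2 = integer(0), a2 = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), z1 = numeric(0),
                      x2 = numeric(0), y2 = numeric(0), z2 = numeric(0),
                      extension = numeric(0), force = numeric(0)))
  p1 <- t(vapply(seq_len(nm), function(m) head_position(state, m, 1),
                 numeric(3)))
  p2 <- t(vapply(seq_len(nm), function(m) head_position(state, m, 2),
                 numeric(3)))
  dbl <- state$m_fil[, 1] > 0 & state$m_fil[, 2] > 0
  ext <- rep(0, nm)
  if (any(dbl)) {
    dv <- min_image(p1[dbl, , drop = FALSE], p2[dbl, , drop = FALSE],
                    state$box)
    ext[dbl] <- sqrt(rowSums(dv^2))
  }
  data.frame(motor = seq_len(nm),
             fil1 = state$m_fil[, 1], a1 = state$m_abs[, 1],
             fil2 = state$m_fil[, 2], a2 = state$m_abs[, 2],
             x1 = p1[, 1], y1 = p1[, 2], z1 = p1[, 3],
             x2 = p2[, 1], y2 = p2[, 2], z2 = p2[, 3],
             extension = ext, force = params$k_link * ext)
}

#' Dump the per-vertex force field to CSV (debugging aid)
#'
#' Writes the steric/depletion, bending and motor-link force components
#' acting on every vertex of the current configuration.
#'
#' @param state an `mt_state`
#' @param params an `mt_params`
#' @param path output CSV path
#' @return the data frame, invisibly
#' @export
write_force_field <- function(state, params, path) {
  Fs <- steric_forces(state, params)
  Fl <- link_forces(state, params)$vertex_forces
  off <- filament_offsets(state)
  Fb <- matrix(0, nrow(state$vert), 3)
  for (i in seq_along(state$fil_nv)) {
    rows <- (off[i] + 1):(off[i] + state$fil_nv[i])
    Fb[rows, ] <- bending_forces(state$vert[rows, , drop = FALSE],
                                 params$kappa)
  }
  df <- data.frame(fil = rep(seq_along(state$fil_nv), state$fil_nv),
                   vertex = sequence(state$fil_nv),
                   x = state$vert[, 1], y = state$vert[, 2],
                   z = state$vert[, 3],
                   fx_steric = Fs[, 1], fy_steric = Fs[, 2],
                   fz_steric = Fs[, 3],
                   fx_bend = Fb[, 1], fy_bend = Fb[, 2], fz_bend = Fb[, 3],
                   fx_link = Fl[, 1], fy_link = Fl[, 2], fz_link = Fl[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
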