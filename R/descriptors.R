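#' Descriptor column order used throughout the classification pipeline
#' @export
DESCRIPTOR_COLS <- c("S", "mobility", "cluster_frac", "fP", "fAP", "fX", "fEnd")

filament_orientations_2d <- function(state) {
  e <- filament_ends(state)
  u <- (e$plus - e$minus)[, 1:2, drop = FALSE]
  n <- sqrt(rowSums(u^2))
  if (any(n < 1e-12)) stop("filament with no in-plane extension")
  u / n
}

#' Windowed scalar nematic order parameter
#'
#' The box is tiled with square windows of side `window` (the last row and
#' column are padded when the box is not a multiple). Each filament is
#' assigned to one window by the x,y position of its end-to-end midpoint.
#' Per window, the 2D orientation tensor `Q = <u x u> - I/2` is built from
#' the normalized x,y components of the minus-to-plus end-to-end vectors;
#' the window order parameter is `S_w = 2 lambda_max(Q)` (the rescaling
#' that maps perfect alignment to 1 in two dimensions), and the global `S`
#' is the filament-count-weighted average over windows. `S` is polarity
#' blind: flipping any filament's orientation leaves it unchanged.
#'
#' @param state an `mt_state`
#' @param window window side (um); default 10
#' @return scalar `S` in `[0, 1]`
#' @export
nematic_order <- function(state, window = 10) {
  u <- filament_orientations_2d(state)
  e <- filament_ends(state)
  mid <- wrap_xy((e$minus + e$plus) / 2, state$box)
  nx <- max(1L, floor(state$box[1] / window + 1e-9))
  ny <- max(1L, floor(state$box[2] / window + 1e-9))
  ix <- pmin(floor(mid[, 1] / window), nx - 1)
  iy <- pmin(floor(mid[, 2] / window), ny - 1)
  w <- as.integer(iy * nx + ix)
  q1 <- tapply(u[, 1]^2, w, mean) - 0.5
  q2 <- tapply(u[, 1] * u[, 2], w, mean)
  nw <- tapply(u[, 1], w, length)
  Sw <- 2 * sqrt(q1^2 + q2^2)
  sum(nw * Sw) / sum(nw)
}

#' Classify motor crosslinks into P, AP, X and End links
#'
#' Every doubly bound motor yields exactly one record. A link is an End
#' link when either head sits within `end_radius` of its filament's plus
#' end; otherwise it is classified by the internal angle between the
#' plus-end-directed local tangents at the two attachment points:
#' P for angles below 60 degrees, X for 60-120 degrees, AP above 120
#' degrees. The End-link fraction is taken over all links,
#' `End / (P + AP + X + End)`; the P/AP/X fractions are taken over the
#' non-end links only.
#'
#' @param state an `mt_state`
#' @param end_radius plus-end proximity threshold (um); default 0.01
#' @return list with `records` (data frame: motor, fil1, fil2, angle
#'   (degrees), class) and `fractions` (named vector fP, fAP, fX, fEnd;
#'   `NaN` where the denominator is empty)
#' @export
classify_links <- function(state, end_radius = 0.01) {
  dbl <- which(state$m_fil[, 1] > 0 & state$m_fil[, 2] > 0)
  rec <- data.frame(motor = integer(0), fil1 = integer(0), fil2 = integer(0),
                    angle = numeric(0), class = character(0))
  if (length(dbl)) {
    rows <- lapply(dbl, function(m) {
      i1 <- state$m_fil[m, 1]; i2 <- state$m_fil[m, 2]
      a1 <- state$m_abs[m, 1]; a2 <- state$m_abs[m, 2]
      t1 <- filament_tangent(state, i1, a1)
      t2 <- filament_tangent(state, i2, a2)
      th <- acos(min(1, max(-1, sum(t1 * t2)))) * 180 / pi
      is_end <- a1 >= state$fil_L[i1] - end_radius ||
                a2 >= state$fil_L[i2] - end_radius
      # angle-bin boundaries carry a tolerance so that exactly 60 and
      # 120 degree geometries land in X despite acos rounding
      cls <- if (is_end) "End"
             else if (th < 60 - 1e-9) "P"
             else if (th <= 120 + 1e-9) "X"
             else "AP"
      list(m, i1, i2, th, cls)
    })
    rec <- data.frame(motor = vapply(rows, `[[`, 0L, 1),
                      fil1 = vapply(rows, `[[`, 0L, 2),
                      fil2 = vapply(rows, `[[`, 0L, 3),
                      angle = vapply(rows, `[[`, 0, 4),
                      class = vapply(rows, `[[`, "", 5))
  }
  n_all <- nrow(rec)
  n_end <- sum(rec$class == "End")
  n_non <- n_all - n_end
  fr <- c(fP = sum(rec$class == "P") / n_non,
          fAP = sum(rec$class == "AP") / n_non,
          fX = sum(rec$class == "X") / n_non,
          fEnd = n_end / n_all)
  list(records = rec, fractions = fr)
}

#' Mean axial minus-end mobility between two frames
#'
#' For each filament, the minimum-image displacement of the minus end over
#' the interval is projected onto the unit vector pointing from the plus
#' end toward the minus end at the earlier time, and divided by the
#' interval. The sign convention makes minus-end-leading sliding (the
#' signature of transport by plus-end-directed crosslinkers) positive.
#' The default interval of 200 s keeps the diffusive contribution
#' negligible relative to motor-driven motion.
#'
#' @param state1 `mt_state` at time t
#' @param state2 `mt_state` at time t + delta_t, same filaments
#' @param delta_t interval (s)
#' @return mean signed speed (um/s)
#' @export
mobility <- function(state1, state2, delta_t = 200) {
  stopifnot(delta_t > 0, length(state1$fil_nv) == length(state2$fil_nv))
  e1 <- filament_ends(state1)
  e2 <- filament_ends(state2)
  axis <- e1$minus - e1$plus
  axis <- axis / sqrt(rowSums(axis^2))
  disp <- min_image(e1$minus, e2$minus, state1$box)
  mean(rowSums(disp * axis)) / delta_t
}

#' Fraction of filaments in the largest motor-connected cluster
#'
#' Filaments are nodes; an edge joins two filaments when at least one
#' doubly bound motor crosslinks them. Returns the size of the largest
#' connected component divided by the number of filaments (so isolated
#' filaments give 1/N and a percolated network gives 1).
#'
#' @param state an `mt_state`
#' @return fraction in `(0, 1]`
#' @export
largest_cluster_fraction <- function(state) {
  n <- length(state$fil_nv)
  dbl <- state$m_fil[, 1] > 0 & state$m_fil[, 2] > 0
  if (!any(dbl)) return(1 / n)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(state$m_fil[dbl, 1], state$m_fil[dbl, 2]))
  max(igraph::components(g)$csize) / n
}

#' The seven-descriptor summary of a trajectory
#'
#' Evaluates the windowed nematic order, minus-end mobility (between the
#' frames at `t_end - delta_t` and `t_end`), largest-cluster fraction and
#' the four crosslink fractions on the final frame. Undefined link
#' fractions (no links of the relevant kind) are reported as 0.
#'
#' @param traj an `mt_traj` (list of `mt_state` frames) or list of frames
#' @param window nematic window side (um)
#' @param delta_t mobility interval (s); the trajectory must contain
#'   frames at `t_end - delta_t` and `t_end` (within half a frame spacing)
#' @param end_radius plus-end proximity threshold (um)
#' @return named numeric vector with the `DESCRIPTOR_COLS` entries
#' @export
descriptor_vector <- function(traj, window = 10, delta_t = 200,
                              end_radius = 0.01) {
  frames <- unclass(traj)
  times <- vapply(frames, function(f) f$t, numeric(1))
  t_end <- max(times)
  i_end <- which.max(times)
  if (delta_t > 0 && t_end > 0) {
    target <- max(t_end - delta_t, min(times))
    i0 <- which.min(abs(times - target))
    if (abs(times[i0] - target) > 1e-6 + 0.1 * delta_t)
      stop("trajectory lacks a frame near t_end - delta_t")
    if (i0 == i_end) stop("trajectory needs two distinct frames for mobility")
    mob <- mobility(frames[[i0]], frames[[i_end]], times[i_end] - times[i0])
  } else {
    mob <- 0
  }
  s <- frames[[i_end]]
  fr <- classify_links(s, end_radius)$fractions
  fr[is.nan(fr)] <- 0
  c(S = nematic_order(s, window), mobility = mob,
    cluster_frac = largest_cluster_fraction(s), fr[c("fP", "fAP", "fX")],
    fEnd = unname(fr["fEnd"]))
}
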