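#' Construct a simulation state
#'
#' A state holds the full configuration at one instant: filament vertex
#' chains (minus end first, equally spaced vertices), the motor table, the
#' box, and the running total polymer length checked against the tubulin
#' budget.
#'
#' Motors are stored as a flat table: `m_fil` (n x 2 integer, 0 = free head),
#' `m_abs` (n x 2, abscissa from the minus end, um) and `m_pos` (n x 3 world
#' position, used while the motor is fully detached; a singly bound motor's
#' free head rides at its bound head's position).
#'
#' @param filaments list of n_i x 3 vertex matrices (um), minus end first
#' @param box `c(Lx, Ly, Lz)` (um)
#' @param m_fil,m_abs,m_pos motor table (see Details); defaults: no motors
#' @param t time (s)
#' @param fixed logical per filament; fixed filaments are immobilized
#' @return an object of class `mt_state`
#' @export
mt_state <- function(filaments, box, m_fil = NULL, m_abs = NULL, m_pos = NULL,
                     t = 0, fixed = NULL) {
  stopifnot(length(filaments) >= 1)
  nv <- vapply(filaments, nrow, integer(1))
  stopifnot(all(nv >= 2))
  seg1 <- vapply(filaments, function(v) sqrt(sum((v[2, ] - v[1, ])^2)),
                 numeric(1))
  L <- (nv - 1) * seg1
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
  if (is.null(fixed)) fixed <- rep(FALSE, length(filaments))
  s <- list(t = t,
            box = as.numeric(box)[1:3],
            fil_nv = nv,
            fil_L = L,
            fil_fixed = as.logical(fixed),
            vert = do.call(rbind, filaments),
            m_fil = m_fil, m_abs = m_abs, m_pos = m_pos,
            total_polymer = sum(L))
  class(s) <- "mt_state"
  validate_state(s)
  s
}

#' Validate a state against its structural invariants
#'
#' Checks equal vertex spacing per filament (1e-6 relative tolerance),
#' consistency of the recomputed total polymer length, bound abscissae in
#' `[0, L]`, and that no motor has both heads on the same filament.
#'
#' @param s an `mt_state`
#' @param Omega optional tubulin budget; if given, checks
#'   `total_polymer <= Omega`
#' @return `s`, invisibly; stops on violation
#' @export
validate_state <- function(s, Omega = NULL) {
  stopifnot(inherits(s, "mt_state"))
  off <- filament_offsets(s)
  for (i in seq_along(s$fil_nv)) {
    v <- s$vert[(off[i] + 1):(off[i] + s$fil_nv[i]), , drop = FALSE]
    d <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
    seg <- s$fil_L[i] / (s$fil_nv[i] - 1)
    if (any(abs(d - seg) > 1e-6 * max(seg, 1)))
      stop("filament ", i, ": unequal vertex spacing")
  }
  if (abs(sum(s$fil_L) - s$total_polymer) > 1e-9 * max(1, s$total_polymer))
    stop("total_polymer inconsistent with filament lengths")
  if (!is.null(Omega) && s$total_polymer > Omega * (1 + 1e-9))
    stop("total_polymer exceeds the tubulin budget Omega")
  if (nrow(s$m_fil) > 0) {
    for (h in 1:2) {
      b <- s$m_fil[, h] > 0
      if (any(b)) {
        a <- s$m_abs[b, h]
        L <- s$fil_L[s$m_fil[b, h]]
        if (any(a < -1e-9 | a > L + 1e-9))
          stop("bound abscissa outside [0, L]")
      }
    }
    both <- s$m_fil[, 1] > 0 & s$m_fil[, 2] > 0
    if (any(both & s$m_fil[, 1] == s$m_fil[, 2]))
      stop("motor with both heads on the same filament")
  }
  invisible(s)
}

#' @export
print.mt_state <- function(x, ...) {
  nb <- rowSums(x$m_fil > 0)
  cat("mt_state: t =", x$t, "s,", length(x$fil_nv), "filaments,",
      nrow(x$m_fil), "motors (", sum(nb == 2), "crosslinking ),\n")
  cat("  total polymer", signif(x$total_polymer, 6), "um, box",
      paste(signif(x$box, 4), collapse = " x "), "um\n")
  invisible(x)
}

#' Row offsets of each filament in the vertex matrix
#' @param s an `mt_state`
#' @return integer vector, `off[i]` = rows before filament i
#' @export
filament_offsets <- function(s) {
  c(0L, cumsum(s$fil_nv))[seq_along(s$fil_nv)]
}

#' Vertices of one filament
#' @param s an `mt_state`
#' @param i filament index
#' @return nv x 3 matrix, minus end first
#' @export
filament_vertices <- function(s, i) {
  off <- filament_offsets(s)[i]
  s$vert[(off + 1):(off + s$fil_nv[i]), , drop = FALSE]
}

#' Point on a filament at a given abscissa
#' @param s an `mt_state`
#' @param i filament index
#' @param a abscissa from the minus end (um), in `[0, L]`
#' @return 3-vector (um)
#' @export
filament_point <- function(s, i, a) {
  v <- filament_vertices(s, i)
  seg <- s$fil_L[i] / (s$fil_nv[i] - 1)
  k <- min(max(floor(a / seg), 0), s$fil_nv[i] - 2)
  u <- a / seg - k
  (1 - u) * v[k + 1, ] + u * v[k + 2, ]
}

#' Unit tangent (plus-end directed) at a given abscissa
#' @inheritParams filament_point
#' @return unit 3-vector
#' @export
filament_tangent <- function(s, i, a) {
  v <- filament_vertices(s, i)
  seg <- s$fil_L[i] / (s$fil_nv[i] - 1)
  k <- min(max(floor(a / seg), 0), s$fil_nv[i] - 2)
  tvec <- v[k + 2, ] - v[k + 1, ]
  tvec / sqrt(sum(tvec^2))
}

#' World position of a motor head
#' @param s an `mt_state`
#' @param m motor index
#' @param h head index (1 or 2)
#' @return 3-vector; for a free head, the motor position (fully free) or the
#'   partner head's position (singly bound)
#' @export
head_position <- function(s, m, h) {
  if (s$m_fil[m, h] > 0)
    return(filament_point(s, s$m_fil[m, h], s$m_abs[m, h]))
  o <- 3 - h
  if (s$m_fil[m, o] > 0)
    return(filament_point(s, s$m_fil[m, o], s$m_abs[m, o]))
  s$m_pos[m, ]
}

#' Minus- and plus-end coordinates of all filaments
#' @param s an `mt_state`
#' @return list with n x 3 matrices `minus` and `plus`
#' @export
filament_ends <- function(s) {
  off <- filament_offsets(s)
  list(minus = s$vert[off + 1L, , drop = FALSE],
       plus  = s$vert[off + s$fil_nv, , drop = FALSE])
}

#' Nucleate the initial state for a parameter set
#'
#' Places `n_fil` straight seeds of length `seg_len` at uniformly random
#' x,y positions in the box mid-plane with orientations uniform in the x-y
#' plane, and `round(motor_ratio * n_fil)` fully detached motors uniformly
#' in the volume.
#'
#' @param params an `mt_params`
#' @param seed RNG seed; defaults to `params$seed`
#' @return an `mt_state` at t = 0
#' @export
nucleate_state <- function(params, seed = params$seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n <- params$n_fil
  L0 <- params$seg_len
  th <- runif(n, 0, 2 * pi)
  p0 <- cbind(runif(n, 0, params$Lx), runif(n, 0, params$Ly), params$Lz / 2)
  u <- cbind(cos(th), sin(th), 0)
  fil <- lapply(seq_len(n), function(i)
    rbind(p0[i, ] - L0 / 2 * u[i, ], p0[i, ] + L0 / 2 * u[i, ]))
  nm <- as.integer(round(params$motor_ratio * n))
  m_pos <- cbind(runif(nm, 0, params$Lx), runif(nm, 0, params$Ly),
                 runif(nm, 0, params$Lz))
  mt_state(fil, c(params$Lx, params$Ly, params$Lz),
           m_fil = matrix(0L, nm, 2), m_abs = matrix(0, nm, 2),
           m_pos = m_pos)
}
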