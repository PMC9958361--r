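#' Box constructor
#'
#' The simulation volume is a thin slab, periodic in x and y, with
#' reflecting walls in z.
#'
#' @param Lx,Ly,Lz box dimensions (um)
#' @return numeric vector `c(Lx, Ly, Lz)` of class `mt_box`
#' @export
sim_box <- function(Lx, Ly, Lz = 0.2) {
  stopifnot(Lx > 0, Ly > 0, Lz > 0)
  structure(c(Lx = Lx, Ly = Ly, Lz = Lz), class = "mt_box")
}

#' Minimum-image displacement in the periodic slab
#'
#' Shortest displacement `pB - pA` with x and y wrapped on the periodic
#' lattice; the z component is never wrapped (reflecting walls).
#' Both arguments may be matrices with one point per row.
#'
#' @param pA,pB 3-vectors or n x 3 matrices (um)
#' @param box a box, `c(Lx, Ly, Lz)`
#' @return displacement with the same shape as the inputs
#' @export
min_image <- function(pA, pB, box) {
  d <- pB - pA
  if (is.matrix(d)) {
    d[, 1] <- d[, 1] - box[1] * round(d[, 1] / box[1])
    d[, 2] <- d[, 2] - box[2] * round(d[, 2] / box[2])
  } else {
    d[1] <- d[1] - box[1] * round(d[1] / box[1])
    d[2] <- d[2] - box[2] * round(d[2] / box[2])
  }
  d
}

#' Wrap points into the primary box image (x and y only)
#'
#' @param p 3-vector or n x 3 matrix (um)
#' @param box a box, `c(Lx, Ly, Lz)`
#' @return wrapped coordinates, x in `[0, Lx)`, y in `[0, Ly)`, z untouched
#' @export
wrap_xy <- function(p, box) {
  if (is.matrix(p)) {
    p[, 1] <- p[, 1] - box[1] * floor(p[, 1] / box[1])
    p[, 2] <- p[, 2] - box[2] * floor(p[, 2] / box[2])
  } else {
    p[1] <- p[1] - box[1] * floor(p[1] / box[1])
    p[2] <- p[2] - box[2] * floor(p[2] / box[2])
  }
  p
}
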