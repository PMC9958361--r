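#' Plot a network configuration
#'
#' Draws the filaments of a state in the x-y plane (minus ends marked),
#' with doubly bound motor crosslinks overlaid. A quick-look diagnostic,
#' not a rendering contract.
#'
#' @param x an `mt_state`
#' @param show_motors overlay crosslinking motors
#' @param ... passed to [graphics::plot()]
#' @return `x`, invisibly
#' @export
plot.mt_state <- function(x, show_motors = TRUE, ...) {
  box <- x$box
  graphics::plot(NA, xlim = c(0, box[1]), ylim = c(0, box[2]), asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  off <- filament_offsets(x)
  for (i in seq_along(x$fil_nv)) {
    v <- wrap_xy(filament_vertices(x, i), box)
    # break wrapped jumps
    jump <- c(FALSE, abs(diff(v[, 1])) > box[1] / 2 |
                     abs(diff(v[, 2])) > box[2] / 2)
    grp <- cumsum(jump)
    for (g in unique(grp)) {
      vv <- v[grp == g, , drop = FALSE]
      if (nrow(vv) > 1)
        graphics::lines(vv[, 1], vv[, 2], col = "grey30")
    }
    graphics::points(v[1, 1], v[1, 2], pch = 16, cex = 0.4, col = "grey50")
  }
  if (show_motors && nrow(x$m_fil)) {
    dbl <- which(x$m_fil[, 1] > 0 & x$m_fil[, 2] > 0)
    for (m in dbl) {
      p1 <- wrap_xy(head_position(x, m, 1), box)
      graphics::points(p1[1], p1[2], pch = 16, cex = 0.3, col = "#00a0a0")
    }
  }
  invisible(x)
}
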