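#' Tubulin-limited growth speed
#'
#' All plus ends share a finite tubulin pool expressed as the total polymer
#' budget `Omega` (um). The common growth speed is
#' `vg = alpha * (1 - total_polymer / Omega)`, never negative; growth stops
#' as the pool is exhausted.
#'
#' @param total_polymer current total filament length (um)
#' @param params an `mt_params`
#' @return growth speed (um/s)
#' @export
growth_speed <- function(total_polymer, params) {
  if (any(total_polymer < 0)) stop("total_polymer must be >= 0")
  if (any(total_polymer > params$Omega * (1 + 1e-9)))
    stop("tubulin budget violated: total_polymer > Omega")
  pmax(params$alpha * (1 - total_polymer / params$Omega), 0)
}

#' Elongate every filament at its plus end for one time step
#'
#' Advances each plus end by `vg * dt` along the terminal segment direction
#' (growth follows the current tip tangent and does not straighten the
#' filament), appends a vertex when the spacing would exceed
#' `1.5 * seg_len`, and re-equalizes the vertex spacing along the contour.
#'
#' @param state an `mt_state`
#' @param params an `mt_params`
#' @return the updated `mt_state`
#' @export
elongate_all <- function(state, params) {
  vg <- growth_speed(state$total_polymer, params)
  dL <- vg * params$dt
  if (dL == 0) return(state)
  off <- filament_offsets(state)
  fil <- lapply(seq_along(state$fil_nv), function(i) {
    v <- filament_vertices(state, i)
    nv <- nrow(v)
    tv <- v[nv, ] - v[nv - 1, ]
    v[nv, ] <- v[nv, ] + dL * tv / sqrt(sum(tv^2))
    L <- state$fil_L[i] + dL
    nv_new <- if (L / (nv - 1) > 1.5 * params$seg_len) nv + 1L else nv
    resample_polyline(v, nv_new, L)
  })
  out <- state
  out$vert <- do.call(rbind, fil)
  out$fil_nv <- vapply(fil, nrow, integer(1))
  out$fil_L <- state$fil_L + dL
  out$total_polymer <- sum(out$fil_L)
  out
}

#' Resample a polyline to equally spaced vertices of prescribed length
#'
#' Samples `n_new` points at equal arc positions along the input polyline,
#' then rebuilds from the minus end with exact spacing `L / (n_new - 1)`,
#' so consecutive vertex distances are exactly equal and the contour length
#' is exactly `L`.
#'
#' @param v nv x 3 vertex matrix
#' @param n_new number of output vertices
#' @param L target contour length (um)
#' @return n_new x 3 matrix
#' @export
resample_polyline <- function(v, n_new, L) {
  d <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  cl <- c(0, cumsum(d))
  Lc <- cl[length(cl)]
  sp <- L / (n_new - 1)
  out <- matrix(0, n_new, 3)
  out[1, ] <- v[1, ]
  w <- v[1, ]
  prevdir <- v[2, ] - v[1, ]
  for (k in 2:n_new) {
    target <- (k - 1) * Lc / (n_new - 1)
    s <- max(1, min(findInterval(target, cl, rightmost.closed = TRUE),
                    nrow(v) - 1))
    den <- cl[s + 1] - cl[s]
    u <- if (den > 0) (target - cl[s]) / den else 0
    smp <- v[s, ] + u * (v[s + 1, ] - v[s, ])
    dir <- smp - w
    dn <- sqrt(sum(dir^2))
    if (dn < 1e-12) { dir <- prevdir; dn <- sqrt(sum(dir^2)) }
    w <- w + sp * dir / dn
    prevdir <- dir
    out[k, ] <- w
  }
  out
}

#' Integrate the growth law alone until the pool is (nearly) depleted
#'
#' Repeatedly applies [elongate_all()] to a state (no mechanics, no motors)
#' until the growth speed falls below `vg_min`, and reports the mean
#' filament length trajectory. With all filaments sharing length `l(t)`
#' the discrete update tracks the closed form
#' `l(t) = (Omega/N)(1 - exp(-alpha N t / Omega)) + l0 exp(-alpha N t / Omega)`.
#'
#' @param params an `mt_params`
#' @param state optional starting `mt_state`; default: nucleated seeds
#' @param vg_min stopping threshold on the growth speed (um/s)
#' @param record_every record the mean length every this many steps
#' @return list with `state`, and data frame `trace` (`t`, `mean_length`)
#' @export
simulate_growth <- function(params, state = NULL, vg_min = 1e-4,
                            record_every = 100L) {
  if (is.null(state)) state <- nucleate_state(params)
  # same per-step update as elongate_all, on per-filament matrices (the
  # full state is only reassembled at the end)
  fil <- lapply(seq_along(state$fil_nv), function(i)
    filament_vertices(state, i))
  L <- state$fil_L
  t <- state$t
  ts <- t
  ml <- mean(L)
  step <- 0L
  while (growth_speed(sum(L), params) >= vg_min) {
    dL <- growth_speed(sum(L), params) * params$dt
    for (i in seq_along(fil)) {
      v <- fil[[i]]
      nv <- nrow(v)
      tv <- v[nv, ] - v[nv - 1, ]
      v[nv, ] <- v[nv, ] + dL * tv / sqrt(sum(tv^2))
      Li <- L[i] + dL
      nv_new <- if (Li / (nv - 1) > 1.5 * params$seg_len) nv + 1L else nv
      fil[[i]] <- resample_polyline(v, nv_new, Li)
      L[i] <- Li
    }
    t <- t + params$dt
    step <- step + 1L
    if (step %% record_every == 0L) {
      ts <- c(ts, t)
      ml <- c(ml, mean(L))
    }
  }
  ts <- c(ts, t)
  ml <- c(ml, mean(L))
  out <- mt_state(fil, state$box, m_fil = state$m_fil,
                  m_abs = state$m_abs, m_pos = state$m_pos, t = t,
                  fixed = state$fil_fixed)
  list(state = out, trace = data.frame(t = ts, mean_length = ml))
}

#' Closed-form mean length under the shared-pool growth law
#'
#' @param t time (s), scalar or vector
#' @param l0 initial length (um)
#' @param params an `mt_params` (uses `alpha`, `Omega`, `n_fil`)
#' @return mean length (um) at `t`
#' @export
growth_closed_form <- function(t, l0, params) {
  r <- params$alpha * params$n_fil / params$Omega
  (params$Omega / params$n_fil) * (1 - exp(-r * t)) + l0 * exp(-r * t)
}
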