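#' Physical constant: thermal energy at ~25 degrees C
#'
#' kT in pN um, consistent with the energy conversions used throughout
#' (0.061 pN um is about 14 kT, 0.25 pN um about 60 kT).
#' @export
KT_PNUM <- 4.11e-3

#' Construct a validated simulation parameter set
#'
#' All quantities are in micrometers, seconds, piconewtons. The pair
#' interaction is repulsive below `d0`, attractive between `d0` and
#' `d0 + d1`, and zero beyond; `Kr` and `Ka` are the two branch stiffnesses.
#' Motors bind within `r_bind` at rate `k_on`, walk toward plus ends with a
#' linear force-velocity law (`v_m`, `f_stall`), and unbind at `k_off_side`
#' from the filament side or `k_off_end` from the plus end. Plus-end growth
#' slows as the shared tubulin budget `Omega` (total polymer length, um) is
#' consumed: vg = alpha * (1 - sum(L_i)/Omega).
#'
#' @param dt integration time step (s)
#' @param eta effective medium viscosity (Pa s)
#' @param kappa filament bending rigidity (pN um^2)
#' @param seg_len target vertex spacing of the discretized filaments (um)
#' @param d0 equilibrium / repulsion range of the pair force (um)
#' @param d1 width of the attractive shell beyond `d0` (um)
#' @param Kr,Ka repulsive and attractive stiffness (pN/um); `Kr >= Ka`
#' @param k_on head binding rate (1/s) within the capture radius `r_bind` (um)
#' @param k_off_side,k_off_end side and plus-end unbinding rates (1/s)
#' @param v_m unloaded motor speed (um/s)
#' @param f_stall stall force (pN)
#' @param k_link Hookean stiffness of the motor crosslink (pN/um)
#' @param D_motor diffusion coefficient of unbound motors (um^2/s)
#' @param alpha initial plus-end growth speed (um/s)
#' @param Omega tubulin budget expressed as total polymer length (um)
#' @param n_fil number of filament seeds nucleated at t = 0
#' @param motor_ratio motors per filament
#' @param Lx,Ly,Lz box dimensions (um); x and y are periodic, z reflecting
#' @param seed RNG seed (integer)
#' @param T_end simulated duration (s)
#' @param kT thermal energy (pN um)
#' @param drag_c calibration factor of the per-vertex drag
#'   gamma = drag_c * 3 * pi * eta * seg_len
#' @return an object of class `mt_params` (a named list)
#' @export
sim_params <- function(dt = 0.02, eta = 2.4, kappa = 20, seg_len = 1.0,
                       d0 = 0.1, d1 = 0.32, Kr = 50, Ka = 0,
                       k_on = 5, r_bind = 0.05,
                       k_off_side = 0.05, k_off_end = 0.2,
                       v_m = 0.03, f_stall = 5, k_link = 30, D_motor = 10,
                       alpha = 0.03, Omega = 100, n_fil = 40,
                       motor_ratio = 16,
                       Lx = 40, Ly = 40, Lz = 0.2,
                       seed = 1L, T_end = 1800,
                       kT = KT_PNUM, drag_c = 0.2) {
  p <- list(dt = dt, eta = eta, kappa = kappa, seg_len = seg_len,
            d0 = d0, d1 = d1, Kr = Kr, Ka = Ka,
            k_on = k_on, r_bind = r_bind,
            k_off_side = k_off_side, k_off_end = k_off_end,
            v_m = v_m, f_stall = f_stall, k_link = k_link,
            D_motor = D_motor, alpha = alpha, Omega = Omega,
            n_fil = as.integer(n_fil), motor_ratio = motor_ratio,
            Lx = Lx, Ly = Ly, Lz = Lz,
            seed = as.integer(seed), T_end = T_end,
            kT = kT, drag_c = drag_c)
  class(p) <- "mt_params"
  validate_params(p)
  p
}

#' Validate a parameter set against its physical invariants
#'
#' Checks positivity of lengths and rates, `Kr >= Ka` (stiff repulsion, soft
#' attraction), and that the tubulin budget can accommodate the initial
#' seeds (`Omega >= n_fil * seg_len`, the nucleation seed length).
#'
#' @param p an `mt_params` object
#' @return `p`, invisibly; stops on violation
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "mt_params"))
  chk <- function(ok, msg) if (!ok) stop("invalid parameters: ", msg, call. = FALSE)
  chk(p$d0 > 0 && p$d1 > 0, "d0 and d1 must be positive")
  chk(p$Kr >= 0 && p$Ka >= 0, "stiffnesses must be non-negative")
  chk(p$Kr >= p$Ka, "Kr must be >= Ka (stiff repulsion, soft attraction)")
  chk(p$v_m >= 0, "v_m must be >= 0")
  chk(p$f_stall > 0, "f_stall must be > 0")
  rates <- c(p$k_on, p$k_off_side, p$k_off_end)
  chk(all(rates >= 0), "rates must be >= 0")
  chk(p$dt > 0, "dt must be > 0")
  chk(p$seg_len > 0 && p$eta > 0 && p$kappa >= 0, "seg_len, eta > 0; kappa >= 0")
  chk(p$Lx > 0 && p$Ly > 0 && p$Lz > 0, "box dimensions must be positive")
  chk(p$Omega >= p$n_fil * p$seg_len,
      "Omega must cover the nucleated seeds (Omega >= n_fil * seg_len)")
  chk(p$T_end >= 0, "T_end must be >= 0")
  invisible(p)
}

#' Preset parameter sets for the published simulation conditions
#'
#' Returns a fully populated parameter set for one of the study protocols.
#' The presets fix the interaction geometry (d0 = 0.1 um, d1 = 0.32 um,
#' Kr = 50 pN/um), the KIF11-like motor (v_m = 0.03 um/s, end dwell
#' 1/k_off_end = 5 s, motor:filament ratio 16), the thin slab (Lz = 0.2 um,
#' Lx = Ly = 16 L by default) and the growth protocol (alpha equal to the
#' motor speed, Omega = density * Lx * Ly, n_fil = Omega / L so that the
#' final mean length is L).
#'
#' @param preset one of `"fig1_lowdens"` (L = 2.5 um, 1.3 um/um^2, Ka = 1.2),
#'   `"fig1_highdens"` (L = 2.5 um, 5 um/um^2, Ka = 1.2),
#'   `"length_sweep"` (Ka = 0, density and L variable) or
#'   `"gliding_mesh"` (L = 10 um, 10 um/um^2, Ka = 0)
#' @param L target mean filament length (um); overrides the preset value
#' @param density total filament length per unit area (um/um^2); overrides
#' @param Ka attractive stiffness (pN/um); overrides
#' @param box optional `c(Lx, Ly)` (um) replacing the default 16 L slab;
#'   `Omega` and `n_fil` are recomputed for the requested density
#' @param T_end simulated duration (s); overrides
#' @param seed RNG seed
#' @param ... further overrides passed to [sim_params()]
#' @return an `mt_params` object with an extra field `L_target`
#' @export
default_params <- function(preset = c("fig1_lowdens", "fig1_highdens",
                                      "length_sweep", "gliding_mesh"),
                           L = NULL, density = NULL, Ka = NULL,
                           box = NULL, T_end = NULL, seed = 1L, ...) {
  preset <- match.arg(preset)
  def <- switch(preset,
    fig1_lowdens  = list(L = 2.5, density = 1.3, Ka = 1.2, T_end = 4800),
    fig1_highdens = list(L = 2.5, density = 5.0, Ka = 1.2, T_end = 4800),
    length_sweep  = list(L = 2.5, density = 2.5, Ka = 0.0, T_end = 3600),
    gliding_mesh  = list(L = 10,  density = 10,  Ka = 0.0, T_end = 3600))
  if (!is.null(L)) def$L <- L
  if (!is.null(density)) def$density <- density
  if (!is.null(Ka)) def$Ka <- Ka
  if (!is.null(T_end)) def$T_end <- T_end
  if (is.null(box)) box <- c(16 * def$L, 16 * def$L)
  Omega <- def$density * box[1] * box[2]
  n_fil <- max(1L, as.integer(round(Omega / def$L)))
  p <- sim_params(Ka = def$Ka, Omega = Omega, n_fil = n_fil,
                  Lx = box[1], Ly = box[2], T_end = def$T_end,
                  seed = seed, ...)
  p$L_target <- def$L
  p$density <- def$density
  validate_params(p)
  p
}

#' @export
print.mt_params <- function(x, ...) {
  cat("mt_params:", x$n_fil, "filaments,",
      round(x$motor_ratio * x$n_fil), "motors, box",
      paste(c(x$Lx, x$Ly, x$Lz), collapse = " x "), "um\n")
  cat("  pair force: d0 =", x$d0, "d1 =", x$d1,
      "Kr =", x$Kr, "Ka =", x$Ka, "pN/um\n")
  cat("  motor: v_m =", x$v_m, "um/s, f_stall =", x$f_stall,
      "pN, k_off_side/end =", x$k_off_side, "/", x$k_off_end, "1/s\n")
  cat("  growth: alpha =", x$alpha, "um/s, Omega =", x$Omega, "um\n")
  invisible(x)
}
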