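#' Read a flat key = value configuration file
#'
#' TOML-style flat text: one `key = value` per line, `#` comments and blank
#' lines ignored. Keys mirror the [sim_params()] field names; in addition
#' `preset`, `L`, `density` and `box` (two comma-separated numbers) select
#' a [default_params()] protocol. Unknown keys are errors.
#'
#' @param path file path
#' @return an `mt_params`
#' @export
read_config <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.+)$", ln))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop("malformed config line: ", ln[bad][1])
  keys <- vapply(kv, `[`, "", 2)
  vals <- trimws(vapply(kv, `[`, "", 3))
  if (anyDuplicated(keys)) stop("duplicate config key: ", keys[duplicated(keys)][1])
  par_fields <- names(formals(sim_params))
  extra <- c("preset", "L", "density", "box")
  unknown <- setdiff(keys, c(par_fields, extra))
  if (length(unknown)) stop("unknown config key: ", paste(unknown, collapse = ", "))
  num <- function(v) {
    x <- suppressWarnings(as.numeric(v))
    if (is.na(x)) stop("non-numeric config value: ", v)
    x
  }
  args <- stats::setNames(as.list(vals), keys)
  if ("preset" %in% keys) {
    preset <- gsub("[\"']", "", args$preset)
    dp <- list(preset = preset)
    if ("L" %in% keys) dp$L <- num(args$L)
    if ("density" %in% keys) dp$density <- num(args$density)
    if ("Ka" %in% keys) dp$Ka <- num(args$Ka)
    if ("T_end" %in% keys) dp$T_end <- num(args$T_end)
    if ("seed" %in% keys) dp$seed <- as.integer(num(args$seed))
    if ("box" %in% keys)
      dp$box <- as.numeric(strsplit(args$box, ",")[[1]])[1:2]
    rest <- setdiff(keys, c(extra, "Ka", "T_end", "seed"))
    for (k in rest) dp[[k]] <- num(args[[k]])
    do.call(default_params, dp)
  } else {
    if (any(c("L", "density", "box") %in% keys))
      stop("L/density/box require a preset key")
    for (k in keys) args[[k]] <- num(args[[k]])
    if ("seed" %in% keys) args$seed <- as.integer(args$seed)
    if ("n_fil" %in% keys) args$n_fil <- as.integer(args$n_fil)
    do.call(sim_params, args)
  }
}

fmt_full <- function(x) formatC(x, digits = 17, format = "g")

#' Write a trajectory to plain-text tables
#'
#' Produces `<prefix>_filaments.csv` (frame, t, fil, L, vertex, x, y, z),
#' `<prefix>_motors.csv` (frame, t, motor, fil1, a1, fil2, a2, x, y, z;
#' fil = 0 marks a free head) and `<prefix>_meta.csv` (box dimensions).
#' Coordinates are written with 17 significant digits so a read-back
#' round-trips to full double precision.
#'
#' @param traj an `mt_traj` or list of `mt_state` frames
#' @param prefix output path prefix
#' @return `prefix`, invisibly
#' @export
write_trajectory <- function(traj, prefix) {
  frames <- unclass(traj)
  ftab <- list(); mtab <- list()
  for (k in seq_along(frames)) {
    s <- frames[[k]]
    idx <- rep(seq_along(s$fil_nv), s$fil_nv)
    vi <- sequence(s$fil_nv)
    ftab[[k]] <- data.frame(frame = k, t = fmt_full(s$t), fil = idx,
                            L = fmt_full(s$fil_L[idx]), vertex = vi,
                            x = fmt_full(s$vert[, 1]),
                            y = fmt_full(s$vert[, 2]),
                            z = fmt_full(s$vert[, 3]))
    if (nrow(s$m_fil) > 0)
      mtab[[k]] <- data.frame(frame = k, t = fmt_full(s$t),
                              motor = seq_len(nrow(s$m_fil)),
                              fil1 = s$m_fil[, 1], a1 = fmt_full(s$m_abs[, 1]),
                              fil2 = s$m_fil[, 2], a2 = fmt_full(s$m_abs[, 2]),
                              x = fmt_full(s$m_pos[, 1]),
                              y = fmt_full(s$m_pos[, 2]),
                              z = fmt_full(s$m_pos[, 3]))
  }
  utils::write.csv(do.call(rbind, ftab), paste0(prefix, "_filaments.csv"),
                   row.names = FALSE, quote = FALSE)
  mt <- if (length(mtab)) do.call(rbind, mtab) else
    data.frame(frame = integer(0), t = character(0), motor = integer(0),
               fil1 = integer(0), a1 = character(0), fil2 = integer(0),
               a2 = character(0), x = character(0), y = character(0),
               z = character(0))
  utils::write.csv(mt, paste0(prefix, "_motors.csv"),
                   row.names = FALSE, quote = FALSE)
  s1 <- frames[[1]]
  utils::write.csv(data.frame(Lx = fmt_full(s1$box[1]),
                              Ly = fmt_full(s1$box[2]),
                              Lz = fmt_full(s1$box[3])),
                   paste0(prefix, "_meta.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(prefix)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param prefix path prefix used when writing
#' @return an `mt_traj`
#' @export
read_trajectory <- function(prefix) {
  ft <- utils::read.csv(paste0(prefix, "_filaments.csv"))
  mt <- utils::read.csv(paste0(prefix, "_motors.csv"))
  meta <- utils::read.csv(paste0(prefix, "_meta.csv"))
  box <- as.numeric(meta[1, c("Lx", "Ly", "Lz")])
  frames <- lapply(sort(unique(ft$frame)), function(k) {
    f <- ft[ft$frame == k, ]
    nv <- tabulate(f$fil)
    L <- f$L[!duplicated(f$fil)]
    m <- mt[mt$frame == k, , drop = FALSE]
    nmrow <- nrow(m)
    vm <- unname(as.matrix(f[, c("x", "y", "z")]))
    new_state(vm, nv, L, box,
              m_fil = if (nmrow) cbind(m$fil1, m$fil2),
              m_abs = if (nmrow) cbind(m$a1, m$a2),
              m_pos = if (nmrow) unname(as.matrix(m[, c("x", "y", "z")])),
              t = f$t[1])
  })
  structure(frames, class = "mt_traj")
}

#' Run a full simulation and summarize it
#'
#' Nucleates the initial configuration, advances the engine to `T_end`
#' with frame snapshots at the requested cadence (the final frame and the
#' frame at `T_end - mobility_dt` are always recorded), computes the
#' seven-descriptor summary, and optionally writes the trajectory and a
#' one-row descriptor CSV. Fully reproducible for a given seed on one
#' platform.
#'
#' @param params an `mt_params` (e.g. from [default_params()] or
#'   [read_config()])
#' @param out optional output path prefix; writes
#'   `<out>_filaments.csv` / `<out>_motors.csv` / `<out>_meta.csv` and
#'   `<out>_descriptors.csv`
#' @param frames_every snapshot cadence (s); `NULL` records only the
#'   frames the descriptors need
#' @param seed RNG seed; defaults to `params$seed`
#' @param window nematic window (um)
#' @param mobility_dt mobility interval (s)
#' @return list with `traj` (an `mt_traj`), `descriptors` (named vector)
#'   and `state` (final `mt_state`)
#' @export
run_simulation <- function(params, out = NULL, frames_every = NULL,
                           seed = params$seed, window = 10,
                           mobility_dt = 200) {
  s0 <- nucleate_state(params, seed = seed)
  n_steps <- as.integer(round(params$T_end / params$dt))
  if (n_steps == 0L) {
    traj <- structure(list(s0), class = "mt_traj")
    d <- descriptor_vector(traj, window = window, delta_t = 0)
  } else {
    dt_mob <- min(mobility_dt, params$T_end)
    snaps <- sort(unique(c(
      if (!is.null(frames_every))
        seq(as.integer(round(frames_every / params$dt)), n_steps,
            by = as.integer(round(frames_every / params$dt))),
      as.integer(round((params$T_end - dt_mob) / params$dt)),
      n_steps)))
    snaps <- snaps[snaps >= 1 & snaps <= n_steps]
    res <- step_state(s0, params, n_steps = n_steps, seed = seed,
                      snapshot_steps = snaps)
    traj <- structure(c(list(s0), res$snapshots), class = "mt_traj")
    d <- descriptor_vector(traj, window = window, delta_t = dt_mob)
  }
  if (!is.null(out)) {
    write_trajectory(traj, out)
    dd <- data.frame(run_id = 1L, density = params$Omega / (params$Lx * params$Ly),
                     L = if (!is.null(params$L_target)) params$L_target else NA,
                     Ka = params$Ka, t(d))
    utils::write.csv(dd, paste0(out, "_descriptors.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  list(traj = traj, descriptors = d,
       state = traj[[length(unclass(traj))]])
}
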