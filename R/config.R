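#' Simulation configuration
#'
#' Collects every parameter of the agent-based shoal model. Lengths are in
#' body lengths L, times in units of T (see package docs), forces in units
#' of v0/T. The defaults are a calibrated set for which a group of N = 3
#' is tristable (intermittent schooling, milling and swarming); they are a
#' tunable model choice, not measured fish parameters.
#'
#' @param n_fish number of agents N.
#' @param v0 cruising speed (L/T); 1 corresponds to 100 mm/s.
#' @param d_phi rotational diffusion constant of the heading noise
#'   (rad^2/T); the heading variance of a free fish grows as `2 d_phi t`.
#' @param arena_radius circular tank radius R in L.
#' @param dt integration time step (T), Euler--Maruyama.
#' @param n_steps number of post-burn-in steps to integrate.
#' @param burn_in steps discarded before recording.
#' @param stride record every `stride`-th step.
#' @param seed integer RNG seed; same seed + config gives bit-identical
#'   output.
#' @param k_wall,lambda_wall wall avoidance: soft exponential repulsion of
#'   magnitude `k_wall * exp(-(R - |r|) / lambda_wall)` pointing to the
#'   arena center.
#' @param k_att,r_eq,r_cut,f_max repulsion--attraction: linear spring
#'   `k_att * (r - r_eq)` toward the neighbor for `r <= r_cut` (repulsive
#'   below the equilibrium distance `r_eq`), magnitude capped at `f_max`.
#' @param k_align,r_align alignment: heading torque
#'   `k_align * sin(phi_j - phi_i) * exp(-r / r_align)` (applied directly
#'   in the heading equation).
#' @param s_hydro,r_reg hydrodynamic coupling: each fish sheds a far-field
#'   2D dipole of strength `s_hydro * v_j` aligned with its heading; others
#'   are advected by the summed dipolar flow (decaying as 1/r^2,
#'   regularized below `r_reg`) and reoriented at the slender-body rotation
#'   rate in the local velocity gradient. Not masked by the field of view.
#' @param fov_deg field-of-view half-angle in degrees: neighbor j affects
#'   the attraction/alignment channels of fish i only if the angle between
#'   i's heading and the line of sight to j is at most `fov_deg`. 180
#'   disables the blind zone.
#' @param speed_model `"fixed"` (speed pinned at v0) or `"variable"`
#'   (speed relaxes to v0 with time constant `tau_v` and responds to the
#'   along-heading force component, floored at `v_floor`).
#' @param tau_v,v_floor variable-speed parameters.
#' @return an object of class `sim_config` (a validated named list).
#' @export
sim_config <- function(n_fish = 3, v0 = 1, d_phi = 0.015,
                       arena_radius = 66.7, dt = 0.05,
                       n_steps = 2e5, burn_in = 1e4, stride = 4, seed = 1,
                       k_wall = 5, lambda_wall = 2,
                       k_att = 1, r_eq = 1, r_cut = 20, f_max = 3,
                       k_align = 0.15, r_align = 3,
                       s_hydro = 0.25, r_reg = 1,
                       fov_deg = 150,
                       speed_model = c("fixed", "variable"),
                       tau_v = 0.1, v_floor = 0.1) {
  speed_model <- match.arg(speed_model)
  cfg <- list(n_fish = as.integer(n_fish), v0 = v0, d_phi = d_phi,
              arena_radius = arena_radius, dt = dt,
              n_steps = as.integer(n_steps), burn_in = as.integer(burn_in),
              stride = as.integer(stride), seed = as.integer(seed),
              k_wall = k_wall, lambda_wall = lambda_wall,
              k_att = k_att, r_eq = r_eq, r_cut = r_cut, f_max = f_max,
              k_align = k_align, r_align = r_align,
              s_hydro = s_hydro, r_reg = r_reg, fov_deg = fov_deg,
              speed_model = speed_model, tau_v = tau_v, v_floor = v_floor)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  nonneg <- c("d_phi", "k_wall", "k_att", "k_align", "s_hydro", "f_max")
  for (p in nonneg)
    if (cfg[[p]] < 0) stopf("%s must be >= 0", p)
  pos <- c("v0", "arena_radius", "dt", "lambda_wall", "r_eq", "r_cut",
           "r_align", "r_reg", "tau_v", "v_floor")
  for (p in pos)
    if (cfg[[p]] <= 0) stopf("%s must be > 0", p)
  if (cfg$fov_deg <= 0 || cfg$fov_deg > 180)
    stopf("fov_deg must be in (0, 180]")
  if (cfg$n_fish < 1) stopf("n_fish must be >= 1")
  if (cfg$n_steps < 1) stopf("n_steps must be >= 1")
  if (cfg$burn_in < 0) stopf("burn_in must be >= 0")
  if (cfg$stride < 1) stopf("stride must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config (units: L = 30 mm, T = 0.3 s unless overridden)\n")
  nm <- names(x)
  for (i in seq_along(nm))
    cat(sprintf("  %-12s %s\n", nm[i], format(x[[i]])))
  invisible(x)
}

#' Read / write a flat key = value configuration file
#'
#' The on-disk format is a flat TOML-style `key = value` list, one per
#' line; `#` starts a comment; strings are unquoted. All keys of
#' [sim_config()] are accepted; missing keys take the defaults.
#'
#' @param path file path.
#' @return `read_sim_config`: a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) stopf("cannot parse config line: '%s'", ln[bad[1]])
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  known <- names(formals(sim_config))
  unk <- setdiff(keys, known)
  if (length(unk)) stopf("unknown config key(s): %s", paste(unk, collapse = ", "))
  args <- lapply(seq_along(keys), function(i) {
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) vals[i] else v
  })
  names(args) <- keys
  do.call(sim_config, args)
}

#' @rdname read_sim_config
#' @param cfg a [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  ln <- c("# shoaldyn simulation config (units: L = 30 mm, T = 0.3 s)",
          sprintf("%s = %s", names(cfg),
                  vapply(cfg, function(v) format(v, digits = 15), "")))
  writeLines(ln, path)
  invisible(path)
}
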