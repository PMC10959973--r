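#' Wall avoidance force
#'
#' Soft exponential repulsion from the circular arena wall: magnitude
#' `k_wall * exp(-(R - |r|) / lambda_wall)` directed from the fish toward
#' the arena center. Defined everywhere, including outside the arena
#' (where it keeps growing exponentially). At the exact center the
#' direction is undefined and the force is zero.
#'
#' @param position numeric length-2 vector, or an `n x 2` matrix of
#'   positions, in L.
#' @param config a [sim_config()].
#' @return a force vector (or `n x 2` matrix), units v0/T.
#' @export
wall_force <- function(position, config) {
  p <- if (is.matrix(position)) position else matrix(position, nrow = 1L)
  r <- sqrt(rowSums(p^2))
  mag <- config$k_wall * exp(-(config$arena_radius - r) / config$lambda_wall)
  f <- -p * ifelse(r > 1e-12, mag / r, 0)
  if (!is.matrix(position)) f <- drop(f)
  f
}

#' Simulator state
#'
#' @param x,y positions (L); `phi` headings in radians, wrapped to
#'   `(-pi, pi]`; `v` speeds (L/T), defaults to 1 for each fish.
#' @return an object of class `sim_state`.
#' @export
sim_state <- function(x, y, phi, v = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(x) == length(phi),
            length(x) == length(v), all(v > 0))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 phi = wrap_angle(as.numeric(phi)), v = as.numeric(v)),
            class = "sim_state")
}

# dipolar flow and velocity gradient at point `at` due to a dipole at
# `src` with heading phi_src and strength s (= s_hydro * v_src).
# Flow u = s * (2 (d.n) n - d) / re^2 with n the unit separation and re
# the distance clamped below at r_reg; for r < r_reg the source point is
# pushed back to distance r_reg along the same direction (bounded field).
dipole_field <- function(at, src, phi_src, s, r_reg) {
  rho <- at - src
  r <- sqrt(sum(rho^2))
  if (r < 1e-12) return(list(u = c(0, 0), G = matrix(0, 2, 2)))
  if (r < r_reg) rho <- rho * (r_reg / r)
  r2 <- sum(rho^2)
  d <- c(cos(phi_src), sin(phi_src))
  dn <- sum(d * rho)
  u <- s * (2 * dn * rho / r2 - d) / r2
  # G_kl = d u_k / d x_l
  G <- s * (2 * outer(rho, d) + 2 * dn * diag(2) + 2 * outer(d, rho)) / r2^2 -
    8 * s * dn * outer(rho, rho) / r2^3
  list(u = u, G = G)
}

#' Pairwise interactions, per channel
#'
#' Reference (pure R) evaluation of the social forces acting on every
#' fish: the repulsion--attraction force and alignment torque (both masked
#' by the field of view) and the hydrodynamic advection + reorientation
#' (felt regardless of vision). Returned per channel so each can be
#' inspected and tested separately; [sim_step()] combines them.
#'
#' @param state a [sim_state()].
#' @param config a [sim_config()].
#' @return list with `att` (`n x 2` force matrix), `align` (length-n
#'   heading torque, rad/T), `hyd_u` (`n x 2` advection velocity),
#'   `hyd_torque` (length-n heading torque).
#' @export
pair_interactions <- function(state, config) {
  n <- length(state$x)
  att <- matrix(0, n, 2)
  align <- numeric(n)
  hyd_u <- matrix(0, n, 2)
  hyd_tq <- numeric(n)
  cos_fov <- cos(config$fov_deg * pi / 180)
  for (i in seq_len(n)) {
    pi_h <- c(cos(state$phi[i]), sin(state$phi[i]))
    pperp <- c(-sin(state$phi[i]), cos(state$phi[i]))
    for (j in seq_len(n)) {
      if (j == i) next
      dx <- state$x[j] - state$x[i]
      dy <- state$y[j] - state$y[i]
      r <- sqrt(dx^2 + dy^2)
      if (r < 1e-12) { dx <- 1e-6; dy <- 0; r <- 1e-6 }  # coincident: jitter
      seen <- (pi_h[1] * dx + pi_h[2] * dy) / r >= cos_fov
      if (seen) {
        if (r <= config$r_cut) {
          f <- config$k_att * (r - config$r_eq)
          f <- max(min(f, config$f_max), -config$f_max)
          att[i, ] <- att[i, ] + f * c(dx, dy) / r
        }
        align[i] <- align[i] +
          config$k_align * sin(state$phi[j] - state$phi[i]) *
          exp(-r / config$r_align)
      }
      if (config$s_hydro > 0) {
        df <- dipole_field(c(state$x[i], state$y[i]),
                           c(state$x[j], state$y[j]),
                           state$phi[j], config$s_hydro * state$v[j],
                           config$r_reg)
        hyd_u[i, ] <- hyd_u[i, ] + df$u
        # slender-body rotation rate in the local flow gradient
        hyd_tq[i] <- hyd_tq[i] + sum(pperp * (df$G %*% pi_h))
      }
    }
  }
  list(att = att, align = align, hyd_u = hyd_u, hyd_torque = hyd_tq)
}

#' One Euler--Maruyama step (reference implementation)
#'
#' Heading update
#' `phi <- phi + dt * ((F_wall + F_att) . e_phi / v + T_align + T_hyd)
#'  + sqrt(2 d_phi dt) xi`,
#' with `e_phi = (-sin phi, cos phi)`, followed by the position update
#' `x <- x + (v cos phi' + u_hyd_x) dt` (and likewise y) using the updated
#' heading. In variable-speed mode the speed relaxes to v0 and responds to
#' the along-heading force component. This pure-R step mirrors the
#' compiled core used by [simulate_shoal()] and is cross-checked against
#' it in the test suite.
#'
#' @param state a [sim_state()].
#' @param config a [sim_config()].
#' @param noise standard-normal deviates, one per fish; `NULL` draws them,
#'   `0` gives the deterministic update.
#' @return the updated `sim_state`.
#' @export
sim_step <- function(state, config, noise = NULL) {
  n <- length(state$x)
  if (is.null(noise)) noise <- rnorm(n)
  noise <- rep_len(noise, n)
  fw <- wall_force(cbind(state$x, state$y), config)
  pint <- pair_interactions(state, config)
  ftot <- fw + pint$att
  eperp_x <- -sin(state$phi)
  eperp_y <- cos(state$phi)
  fproj <- ftot[, 1] * eperp_x + ftot[, 2] * eperp_y
  dphi <- config$dt * (fproj / state$v + pint$align + pint$hyd_torque) +
    sqrt(2 * config$d_phi * config$dt) * noise
  v_new <- state$v
  if (config$speed_model == "variable") {
    fpar <- ftot[, 1] * cos(state$phi) + ftot[, 2] * sin(state$phi)
    v_new <- state$v +
      config$dt * ((config$v0 - state$v) / config$tau_v + fpar)
    v_new <- pmax(v_new, config$v_floor)
  }
  phi_new <- wrap_angle(state$phi + dphi)
  x_new <- state$x + (v_new * cos(phi_new) + pint$hyd_u[, 1]) * config$dt
  y_new <- state$y + (v_new * sin(phi_new) + pint$hyd_u[, 2]) * config$dt
  if (any(!is.finite(c(x_new, y_new, phi_new, v_new))))
    stopf("non-finite state after update (step diverged)")
  sim_state(x_new, y_new, phi_new, v_new)
}

#' Default initial condition: a loose cluster at the arena center
#' @keywords internal
init_state <- function(config) {
  n <- config$n_fish
  r0 <- 2 + sqrt(n)
  rr <- r0 * sqrt(runif(n))
  th <- runif(n, -pi, pi)
  sim_state(rr * cos(th), rr * sin(th), runif(n, -pi, pi),
            rep(config$v0, n))
}

#' Run the agent-based shoal simulation
#'
#' Integrates the overdamped heading dynamics (see [sim_step()]) with the
#' compiled core, discards the burn-in, and records every `stride`-th step
#' as a 2D [fish_trajectory()]. The recorded trajectory carries the exact
#' instantaneous velocities (including hydrodynamic advection) as an
#' analytic sidecar, and the heading matrix as attribute `"headings"`.
#' The same seed and config give bit-identical output.
#'
#' @param config a [sim_config()].
#' @param init optional [sim_state()] initial condition; default: fish
#'   scattered uniformly in a small disc at the arena center with uniform
#'   random headings (drawn after seeding, so still reproducible).
#' @return a [fish_trajectory()]; attribute `"headings"` holds the
#'   `(frame, fish)` heading matrix and attribute `"n_coincident"` counts
#'   regularized coincident-pair events.
#' @export
simulate_shoal <- function(config, init = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(init)) init <- init_state(config)
  stopifnot(inherits(init, "sim_state"),
            length(init$x) == config$n_fish)
  shoal_log("simulate", n_fish = config$n_fish, steps = config$n_steps,
            dt = config$dt, seed = config$seed)
  res <- sim_core_cpp(init$x, init$y, init$phi, init$v, unclass(config),
                      config$n_steps, config$burn_in, config$stride,
                      config$speed_model == "variable")
  nrec <- nrow(res$x)
  pos <- array(NA_real_, c(nrec, config$n_fish, 2))
  pos[, , 1] <- res$x
  pos[, , 2] <- res$y
  vel <- array(NA_real_, c(nrec, config$n_fish, 2))
  vel[, , 1] <- res$vx
  vel[, , 2] <- res$vy
  traj <- fish_trajectory(
    pos, frame_interval = config$dt * config$stride * 0.3,
    body_length_mm = 30, time_unit_s = 0.3, velocities = vel)
  attr(traj, "headings") <- res$phi
  attr(traj, "speeds") <- res$v
  attr(traj, "n_coincident") <- res$n_coincident
  attr(traj, "config") <- config
  traj
}
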