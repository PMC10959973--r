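#' Analytic fixture: a perfectly polarized school
#'
#' `n` fish in single file along the common heading, all moving with
#' identical velocity, so the polarization order parameter is exactly 1 at
#' every frame. The exact velocities are attached as an analytic sidecar.
#'
#' @param n number of fish (>= 1).
#' @param spacing gap between consecutive fish (L).
#' @param heading common swimming direction (radians).
#' @param n_frames number of frames.
#' @param speed common speed (L/T).
#' @param frame_interval seconds per frame (default 0.3 s = 1 T).
#' @return a [fish_trajectory()] with velocity sidecar.
#' @export
perfect_school <- function(n, spacing = 1, heading = 0, n_frames = 10,
                           speed = 1, frame_interval = 0.3) {
  if (n < 1) stopf("perfect_school needs n >= 1")
  dir <- c(cos(heading), sin(heading))
  t_T <- (seq_len(n_frames) - 1)  # frame_interval is 1 T by default
  dt_T <- frame_interval / 0.3
  pos <- array(NA_real_, c(n_frames, n, 2))
  vel <- array(NA_real_, c(n_frames, n, 2))
  for (k in seq_len(n)) {
    base <- (k - 1) * spacing * dir
    pos[, k, 1] <- base[1] + speed * dir[1] * t_T * dt_T
    pos[, k, 2] <- base[2] + speed * dir[2] * t_T * dt_T
    vel[, k, 1] <- speed * dir[1]
    vel[, k, 2] <- speed * dir[2]
  }
  fish_trajectory(pos, frame_interval = frame_interval, velocities = vel)
}

#' Analytic fixture: a perfect mill
#'
#' `n` fish equally spaced on a circle about the origin, all rotating with
#' the same handedness (counter-clockwise for positive `angular_speed`)
#' with exactly tangential velocities, so the rotation order parameter is
#' exactly 1 at every frame. Angular positions start at 0 for fish 1.
#'
#' @param n number of fish (>= 2).
#' @param radius mill radius (L), > 0.
#' @param angular_speed rotation rate (rad/T).
#' @param n_frames number of frames.
#' @param frame_interval seconds per frame.
#' @return a [fish_trajectory()] with velocity sidecar.
#' @export
perfect_mill <- function(n, radius = 2, angular_speed = 0.5, n_frames = 10,
                         frame_interval = 0.3) {
  if (n < 2) stopf("perfect_mill needs n >= 2")
  if (radius <= 0) stopf("radius must be > 0")
  dt_T <- frame_interval / 0.3
  pos <- array(NA_real_, c(n_frames, n, 2))
  vel <- array(NA_real_, c(n_frames, n, 2))
  for (f in seq_len(n_frames)) {
    th <- 2 * pi * (seq_len(n) - 1) / n + angular_speed * (f - 1) * dt_T
    pos[f, , 1] <- radius * cos(th)
    pos[f, , 2] <- radius * sin(th)
    vel[f, , 1] <- -radius * angular_speed * sin(th)
    vel[f, , 2] <- radius * angular_speed * cos(th)
  }
  fish_trajectory(pos, frame_interval = frame_interval, velocities = vel)
}

#' Analytic fixture: an uncorrelated swarm
#'
#' Positions uniform in a disc, headings uniform on the circle, unit
#' speeds, independent across fish and frames. The mean polarization of n
#' random unit vectors is the Rayleigh mean `sqrt(pi / (4 n))`.
#'
#' @param n number of fish.
#' @param region_radius disc radius (L).
#' @param n_frames number of frames.
#' @param seed RNG seed; the fixture is exactly reproducible from
#'   (parameters, seed).
#' @param frame_interval seconds per frame.
#' @return a [fish_trajectory()] with velocity sidecar.
#' @export
random_swarm <- function(n, region_radius = 5, n_frames = 100, seed = 1,
                         frame_interval = 0.3) {
  if (n < 1) stopf("random_swarm needs n >= 1")
  set.seed(seed)
  m <- n_frames * n
  rr <- region_radius * sqrt(runif(m))
  th <- runif(m, -pi, pi)
  hd <- runif(m, -pi, pi)
  pos <- array(NA_real_, c(n_frames, n, 2))
  vel <- array(NA_real_, c(n_frames, n, 2))
  pos[, , 1] <- rr * cos(th)
  pos[, , 2] <- rr * sin(th)
  vel[, , 1] <- cos(hd)
  vel[, , 2] <- sin(hd)
  fish_trajectory(pos, frame_interval = frame_interval, velocities = vel)
}

#' Analytic fixture: ideal-gas frames
#'
#' Positions independently uniform in a disc, frame after frame: the exact
#' null for Kirkwood-superposition testing, where the observed three-body
#' map and the superposition prediction agree up to sampling error (and
#' residual boundary effects of the finite disc).
#'
#' @inheritParams random_swarm
#' @return a [fish_trajectory()] with velocity sidecar (random unit
#'   headings, irrelevant for position statistics).
#' @export
ideal_gas_frames <- function(n, region_radius = 5, n_frames = 1000,
                             seed = 1, frame_interval = 0.3) {
  if (n < 3) stopf("ideal_gas_frames needs n >= 3")
  random_swarm(n, region_radius = region_radius, n_frames = n_frames,
               seed = seed, frame_interval = frame_interval)
}
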