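# Comoving-frame pair correlations.
#
# The comoving frame of a focal fish has x' along its heading and y' 90
# degrees counter-clockwise from it; for 3D data the horizontal components
# are used and the vertical separation is marginalized.

# horizontal heading angles (nf x np matrix), NA where undefined
heading_matrix <- function(vel, speed_floor = 1e-6) {
  v <- vel$v
  nf <- dim(v)[1L]; np <- dim(v)[2L]
  vx <- v[, , 1]; vy <- v[, , 2]
  dim(vx) <- dim(vy) <- c(nf, np)
  sp <- sqrt(vx^2 + vy^2)
  ang <- atan2(vy, vx)
  ang[is.na(sp) | sp < speed_floor] <- NA_real_
  ang
}

#' Comoving-frame coordinates of one fish relative to another
#'
#' Expresses `r_other - r_focal` in the frame attached to the focal fish:
#' x' along the focal (horizontal-plane) heading, y' 90 degrees
#' counter-clockwise from it.
#'
#' @param traj a [fish_trajectory()].
#' @param vel matching `fish_velocity`.
#' @param frame frame index (position in the series, not the raw frame
#'   number).
#' @param focal,other fish ids or indices.
#' @return numeric `c(x', y')` in L.
#' @export
comoving_coordinates <- function(traj, vel = trajectory_velocities(traj),
                                 frame, focal, other) {
  fi <- if (is.character(focal)) match(focal, traj$ids) else as.integer(focal)
  oi <- if (is.character(other)) match(other, traj$ids) else as.integer(other)
  h <- heading_matrix(vel)[frame, fi]
  if (is.na(h)) stopf("focal heading undefined at frame %d", frame)
  dx <- traj$positions[frame, oi, 1] - traj$positions[frame, fi, 1]
  dy <- traj$positions[frame, oi, 2] - traj$positions[frame, fi, 2]
  c(cos(h) * dx + sin(h) * dy, -sin(h) * dx + cos(h) * dy)
}

# frames (indices into the series) passing a state filter
state_frames <- function(traj, states = NULL, state_filter = NULL) {
  nf <- n_frames(traj)
  if (is.null(state_filter) || is.null(states)) return(seq_len(nf))
  idx <- match(traj$frames, states$frame)
  keep <- !is.na(idx) & !is.na(states$state[idx]) &
    as.character(states$state[idx]) == state_filter
  which(keep)
}

#' Comoving-frame pair-correlation map g2(x', y')
#'
#' Histogram of neighbor positions in the focal fish's comoving frame,
#' accumulated over all ordered (focal, other) pairs -- or, in nearest
#' mode, over each focal fish and its nearest neighbor only -- and over
#' the frames passing the state filter. The intensity is normalized by
#' its maximum, the usual convention for these maps.
#'
#' @param traj a [fish_trajectory()].
#' @param vel matching velocities.
#' @param pair_mode `"all"` (every ordered pair) or `"nearest"` (one
#'   sample per focal fish per frame: its nearest neighbor).
#' @param states an `order_series` from [order_parameters()] (needed with
#'   `state_filter`).
#' @param state_filter one of the state labels, or `NULL` for all frames.
#' @param bin bin width (L). @param extent half-extent of the map (L).
#' @param speed_floor heading floor.
#' @return object of class `comoving_map`: bin `xbreaks`/`ybreaks`,
#'   integer `counts` (x' along rows), `intensity` (max-normalized),
#'   `n_samples`, `pair_mode`, `state_filter`.
#' @export
g2_map <- function(traj, vel = trajectory_velocities(traj),
                   pair_mode = c("all", "nearest"),
                   states = NULL, state_filter = NULL,
                   bin = 0.2, extent = 5, speed_floor = 1e-6) {
  pair_mode <- match.arg(pair_mode)
  np <- n_fish(traj)
  if (np < 2) stopf("need at least 2 fish")
  frames <- state_frames(traj, states, state_filter)
  if (!length(frames)) stopf("no frames pass the state filter")
  hd <- heading_matrix(vel, speed_floor)
  pos <- traj$positions
  nb <- as.integer(round(2 * extent / bin))
  counts <- matrix(0L, nb, nb)
  n_samp <- 0L
  px <- pos[, , 1]; py <- pos[, , 2]
  dim(px) <- dim(py) <- c(n_frames(traj), np)
  for (i in seq_len(np)) {
    h <- hd[frames, i]
    ok_f <- !is.na(h)
    if (pair_mode == "nearest") {
      d2 <- matrix(Inf, length(frames), np)
      for (j in seq_len(np)) {
        if (j == i) next
        d2[, j] <- (px[frames, j] - px[frames, i])^2 +
          (py[frames, j] - py[frames, i])^2
      }
      jn <- max.col(-d2, ties.method = "first")
      dx <- px[cbind(frames, jn)] - px[frames, i]
      dy <- py[cbind(frames, jn)] - py[frames, i]
      sel <- ok_f & is.finite(dx)
      xp <- cos(h[sel]) * dx[sel] + sin(h[sel]) * dy[sel]
      yp <- -sin(h[sel]) * dx[sel] + cos(h[sel]) * dy[sel]
      acc <- accumulate2d(counts, xp, yp, -extent, bin, nb)
      counts <- acc$counts
      n_samp <- n_samp + acc$n
    } else {
      for (j in seq_len(np)) {
        if (j == i) next
        dx <- px[frames, j] - px[frames, i]
        dy <- py[frames, j] - py[frames, i]
        sel <- ok_f & !is.na(dx)
        xp <- cos(h[sel]) * dx[sel] + sin(h[sel]) * dy[sel]
        yp <- -sin(h[sel]) * dx[sel] + cos(h[sel]) * dy[sel]
        acc <- accumulate2d(counts, xp, yp, -extent, bin, nb)
        counts <- acc$counts
        n_samp <- n_samp + acc$n
      }
    }
  }
  if (n_samp == 0L) stopf("no eligible samples")
  intensity <- counts / max(counts)
  structure(list(xbreaks = seq(-extent, extent, by = bin),
                 ybreaks = seq(-extent, extent, by = bin),
                 counts = counts, intensity = intensity,
                 n_samples = n_samp, pair_mode = pair_mode,
                 state_filter = state_filter %||% "none"),
            class = "comoving_map")
}

# fraction of a disc of radius R that overlaps the same disc displaced by
# r: the ideal-gas pair-distance edge factor for uniform points in a disc
disc_overlap <- function(r, R) {
  q <- pmin(r / (2 * R), 1)
  (2 / pi) * (acos(q) - q * sqrt(1 - q^2))
}

# histogram (xp, yp) into the counts matrix
accumulate2d <- function(counts, xp, yp, lo, bin, nb) {
  i <- bin_index(xp, lo, bin, nb)
  j <- bin_index(yp, lo, bin, nb)
  ok <- !is.na(i) & !is.na(j)
  if (any(ok)) {
    idx <- (i[ok] - 1L) + (j[ok] - 1L) * nb + 1L
    counts <- counts + matrix(tabulate(idx, nbins = nb * nb), nb, nb)
  }
  # every sampled pair counts toward n, inside the map extent or not
  list(n = length(xp), counts = counts)
}

#' @export
print.comoving_map <- function(x, ...) {
  cat(sprintf("comoving_map (%s pairs, state %s): %dx%d bins, %d samples\n",
              x$pair_mode, x$state_filter, nrow(x$counts), ncol(x$counts),
              x$n_samples))
  invisible(x)
}

#' Radial pair correlation g2(r)
#'
#' Histogram of pairwise distances divided by the shell measure
#' (`2 pi r dr` in 2D, `4 pi r^2 dr` in 3D), normalized by its maximum.
#' `r_max`, the location of the principal peak, is the bin center of the
#' global maximum.
#'
#' @param traj a [fish_trajectory()].
#' @param states,state_filter see [g2_map()].
#' @param bin radial bin width (L).
#' @param r_range range of distances, default `c(0, 10)`.
#' @param domain_radius optional radius of the disc the positions are
#'   sampled in (2D only). When given, counts are additionally divided by
#'   the analytic disc--disc overlap factor, the exact ideal-gas edge
#'   correction for a bounded sampling region; for an ideal gas the
#'   corrected profile is flat. Leave `NULL` (no correction) when the
#'   sampling domain is unknown or much larger than the distances probed.
#' @return data.frame of class `radial_g2` with columns `r` (bin centers)
#'   and `g2` (max-normalized); attributes `r_max`, `counts`, `n_samples`,
#'   `state_filter`, `ndim`.
#' @export
radial_g2 <- function(traj, states = NULL, state_filter = NULL,
                      bin = 0.25, r_range = c(0, 10), domain_radius = NULL) {
  np <- n_fish(traj)
  if (np < 2) stopf("need at least 2 fish")
  frames <- state_frames(traj, states, state_filter)
  if (!length(frames)) stopf("no frames pass the state filter")
  pos <- traj$positions
  nd <- traj$ndim
  nb <- as.integer(round(diff(r_range) / bin))
  cnt <- numeric(nb)
  n_samp <- 0L
  for (i in seq_len(np - 1L)) {
    for (j in (i + 1L):np) {
      d2 <- 0
      for (k in seq_len(nd))
        d2 <- d2 + (pos[frames, j, k] - pos[frames, i, k])^2
      d <- sqrt(d2[!is.na(d2)])
      n_samp <- n_samp + length(d)
      bi <- bin_index(d, r_range[1], bin, nb)
      bi <- bi[!is.na(bi)]
      if (length(bi)) cnt <- cnt + tabulate(bi, nbins = nb)
    }
  }
  if (n_samp == 0L) stopf("no samples")
  centers <- r_range[1] + (seq_len(nb) - 0.5) * bin
  shell <- if (nd == 2L) 2 * pi * centers * bin else 4 * pi * centers^2 * bin
  g <- cnt / shell
  if (!is.null(domain_radius)) {
    if (nd != 2L) stopf("domain_radius edge correction is 2D only")
    a <- disc_overlap(centers, domain_radius)
    g <- ifelse(a > 0, g / a, NA_real_)
  }
  gmax <- max(g, na.rm = TRUE)
  if (gmax > 0) g <- g / gmax
  out <- data.frame(r = centers, g2 = g)
  attr(out, "r_max") <- centers[which.max(g)]
  attr(out, "domain_radius") <- domain_radius
  attr(out, "counts") <- cnt
  attr(out, "n_samples") <- n_samp
  attr(out, "state_filter") <- state_filter %||% "none"
  attr(out, "ndim") <- nd
  attr(out, "bin") <- bin
  class(out) <- c("radial_g2", "data.frame")
  out
}

#' Separation window around the principal g2 peak
#'
#' @param radial a [radial_g2()] result.
#' @param half_width window half-width (L), default 0.25.
#' @return `c(r_lo, r_hi)` around `r_max` (floored at 0).
#' @export
peak_window <- function(radial, half_width = 0.25) {
  rm <- attr(radial, "r_max")
  c(max(rm - half_width, 0), rm + half_width)
}

#' Detect and label peaks of a comoving map
#'
#' Finds local maxima of the map intensity above `floor` times the global
#' maximum (8-neighborhood) and labels them by position in the comoving
#' frame: `beta` for the front peak (`x' > 0`, `|y'| < y_tol`), `alpha` /
#' `gamma` for the left / right side peaks (`y' >= y_tol` / `<= -y_tol`),
#' `other` otherwise (e.g. a rear lobe).
#'
#' @param map a `comoving_map` from [g2_map()].
#' @param floor relative height floor, default 0.5.
#' @param y_tol lateral tolerance separating front from side peaks (L).
#' @return data.frame with columns `label`, `x`, `y`, `height`, sorted by
#'   decreasing height.
#' @export
detect_peaks <- function(map, floor = 0.5, y_tol = 0.5) {
  stopifnot(inherits(map, "comoving_map"))
  z <- map$intensity
  if (all(z == 0)) stopf("empty map")
  nb <- nrow(z)
  xc <- (map$xbreaks[-1] + map$xbreaks[-length(map$xbreaks)]) / 2
  yc <- (map$ybreaks[-1] + map$ybreaks[-length(map$ybreaks)]) / 2
  peaks <- list()
  for (i in seq_len(nb)) {
    for (j in seq_len(nb)) {
      h <- z[i, j]
      if (h < floor) next
      ii <- max(1, i - 1):min(nb, i + 1)
      jj <- max(1, j - 1):min(nb, j + 1)
      nbh <- z[ii, jj]
      if (h < max(nbh)) next
      if (sum(nbh == h) > 1 && !(i == which(z == max(z), arr.ind = TRUE)[1])) {
        # plateau: keep only the lexicographically first bin
        w <- which(nbh == h, arr.ind = TRUE)
        gi <- ii[w[, 1]]; gj <- jj[w[, 2]]
        if (any(gi < i | (gi == i & gj < j))) next
      }
      peaks[[length(peaks) + 1L]] <- data.frame(x = xc[i], y = yc[j],
                                                height = h)
    }
  }
  if (!length(peaks)) stopf("no peaks above the floor")
  pk <- do.call(rbind, peaks)
  lab <- ifelse(abs(pk$y) < y_tol & pk$x > 0, "beta",
                ifelse(pk$y >= y_tol, "alpha",
                       ifelse(pk$y <= -y_tol, "gamma", "other")))
  out <- data.frame(label = lab, pk)
  out[order(-out$height), , drop = FALSE]
}
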