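# Three-body statistics: bond angles, observed g3 maps under a
# constrained reference pair, Kirkwood superposition predictions, and
# their discrepancy.

#' Orientation condition on the reference pair
#'
#' Selects reference-pair configurations by relative orientation:
#' `side_by_side` requires nearly parallel headings with the separation
#' roughly perpendicular to the mean heading; `head_to_tail` requires
#' nearly parallel headings with the separation roughly along the mean
#' heading.
#'
#' @param mode `"none"`, `"side_by_side"` or `"head_to_tail"`.
#' @param heading_tol maximum heading misalignment (degrees, in (0, 90)).
#' @param sep_tol maximum deviation of the separation direction from the
#'   target direction (degrees, in (0, 90)).
#' @return an object of class `orientation_condition`.
#' @export
orientation_condition <- function(mode = c("none", "side_by_side",
                                           "head_to_tail"),
                                  heading_tol = 30, sep_tol = 30) {
  mode <- match.arg(mode)
  if (mode != "none" &&
      (heading_tol <= 0 || heading_tol >= 90 || sep_tol <= 0 || sep_tol >= 90))
    stopf("orientation thresholds must lie in (0, 90) degrees")
  structure(list(mode = mode, heading_tol = heading_tol, sep_tol = sep_tol),
            class = "orientation_condition")
}

#' Does a reference pair satisfy an orientation condition?
#'
#' For `head_to_tail` the ordering matters: `fish1` must be the follower
#' and `fish2` the leader (separation from 1 to 2 pointing along the mean
#' heading). `side_by_side` is symmetric in the pair.
#'
#' @param traj a [fish_trajectory()]; `vel` matching velocities.
#' @param frame frame index into the series.
#' @param fish1,fish2 indices of the reference pair.
#' @param cond an [orientation_condition()].
#' @return `TRUE`/`FALSE` (`FALSE` if a heading is undefined);
#'   mode `"none"` is always `TRUE`.
#' @export
orientation_filter <- function(traj, vel, frame, fish1, fish2, cond) {
  if (cond$mode == "none") return(TRUE)
  hd <- heading_matrix(vel)
  h1 <- hd[frame, fish1]; h2 <- hd[frame, fish2]
  if (is.na(h1) || is.na(h2)) return(FALSE)
  if (abs(wrap_angle(h1 - h2)) > cond$heading_tol * pi / 180) return(FALSE)
  dx <- traj$positions[frame, fish2, 1] - traj$positions[frame, fish1, 1]
  dy <- traj$positions[frame, fish2, 2] - traj$positions[frame, fish1, 2]
  sep_ang <- atan2(dy, dx)
  hm <- atan2(sin(h1) + sin(h2), cos(h1) + cos(h2))  # mean heading
  dev <- abs(wrap_angle(sep_ang - hm))
  tol <- cond$sep_tol * pi / 180
  if (cond$mode == "head_to_tail") dev <= tol
  else abs(dev - pi / 2) <= tol
}

#' Three-fish bond-angle distribution
#'
#' For every frame of a 3-fish trajectory and every vertex of the
#' triangle, the angle at that vertex between the two bond vectors is
#' included when both incident bonds lie in the separation window
#' (typically the principal-peak window of the per-state g2, see
#' [peak_window()]). Returns the normalized histogram on [0, 180]
#' degrees.
#'
#' @param traj a [fish_trajectory()] with exactly 3 fish.
#' @param window `c(r_lo, r_hi)` bond-eligibility window (L).
#' @param states,state_filter see [g2_map()].
#' @param bin_width histogram bin width in degrees (default 10).
#' @return data.frame of class `bond_angle_distribution` with columns
#'   `angle` (bin centers, degrees) and `prob` (sums to 1); attributes
#'   `counts`, `n_samples`, `window`, `state_filter`.
#' @export
bond_angles <- function(traj, window, states = NULL, state_filter = NULL,
                        bin_width = 10) {
  if (n_fish(traj) != 3L)
    stopf("bond_angles needs exactly 3 fish (pass an F_3 group or one F_N^3 subgroup)")
  stopifnot(length(window) == 2L, window[1] < window[2])
  frames <- state_frames(traj, states, state_filter)
  if (!length(frames)) stopf("no frames pass the state filter")
  pos <- traj$positions
  nd <- traj$ndim
  getd <- function(a, b) {  # bond vectors a -> b over frames
    m <- sapply(seq_len(nd), function(k) pos[frames, b, k] - pos[frames, a, k])
    if (length(frames) == 1L) m <- matrix(m, nrow = 1L)
    m
  }
  nb <- as.integer(ceiling(180 / bin_width))
  cnt <- numeric(nb)
  n_samp <- 0L
  verts <- list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  for (vt in verts) {
    b1 <- getd(vt[1], vt[2])
    b2 <- getd(vt[1], vt[3])
    l1 <- sqrt(rowSums(b1^2))
    l2 <- sqrt(rowSums(b2^2))
    ok <- !is.na(l1) & !is.na(l2) &
      l1 >= window[1] & l1 <= window[2] &
      l2 >= window[1] & l2 <= window[2]
    if (!any(ok)) next
    cosang <- rowSums(b1 * b2)[ok] / (l1[ok] * l2[ok])
    ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
    bi <- bin_index(ang, 0, bin_width, nb)
    cnt <- cnt + tabulate(bi[!is.na(bi)], nbins = nb)
    n_samp <- n_samp + sum(ok)
  }
  if (n_samp == 0L) stopf("no bond pairs fall in the window")
  out <- data.frame(angle = (seq_len(nb) - 0.5) * bin_width,
                    prob = cnt / sum(cnt))
  attr(out, "counts") <- cnt
  attr(out, "n_samples") <- n_samp
  attr(out, "window") <- window
  attr(out, "state_filter") <- state_filter %||% "none"
  class(out) <- c("bond_angle_distribution", "data.frame")
  out
}

# midpoint-frame coordinates of the third fish for ordered pair (a, b):
# origin at (r_a + r_b)/2, x-tilde along r_b - r_a
midframe_coords <- function(pos, frames, a, b, third) {
  dx <- pos[frames, b, 1] - pos[frames, a, 1]
  dy <- pos[frames, b, 2] - pos[frames, a, 2]
  r12 <- sqrt(dx^2 + dy^2)
  ox <- (pos[frames, a, 1] + pos[frames, b, 1]) / 2
  oy <- (pos[frames, a, 2] + pos[frames, b, 2]) / 2
  tx <- pos[frames, third, 1] - ox
  ty <- pos[frames, third, 2] - oy
  cc <- dx / r12; ss <- dy / r12
  list(x = cc * tx + ss * ty, y = -ss * tx + cc * ty, r12 = r12,
       ox = ox, oy = oy, cc = cc, ss = ss)
}

#' Observed three-body correlation map g3
#'
#' Conditions one pair of a 3-fish group to separations `|r_12|` inside
#' `r12_window` (and, optionally, to an orientation condition), then
#' histograms the third fish's position in the frame whose origin is the
#' pair midpoint and whose x-axis lies along `r_12`. Unconditioned maps
#' are symmetrized over the two pair orderings and over the x-mirror;
#' `head_to_tail` maps orient the x-axis from follower to leader.
#'
#' @param traj a 2D [fish_trajectory()] with exactly 3 fish.
#' @param r12_window `c(r_lo, r_hi)` window on the reference-pair
#'   separation, typically [peak_window()] of [radial_g2()].
#' @param orientation an [orientation_condition()].
#' @param vel velocities (needed for orientation conditions).
#' @param states,state_filter see [g2_map()].
#' @param bin bin width (L). @param extent map half-extent (L).
#' @param domain_radius optional radius of the disc the positions are
#'   sampled in. When given, each bin's count is divided by the matched
#'   ideal-gas reference -- the fraction of the qualifying reference-pair
#'   geometries for which that bin, mapped back to the lab frame, falls
#'   inside the disc. This removes the boundary imprint of a finite
#'   sampling region (see [radial_g2()]); for an ideal gas the corrected
#'   map is flat.
#' @return object of class `triplet_map`: `xbreaks`, `ybreaks`, `counts`,
#'   `ref` (edge reference, `NULL` without correction), `g3`
#'   (max-normalized), `g3k` (`NULL` until [kirkwood_map()] fills it),
#'   `r12_window`, `orientation`, `n_samples`.
#' @export
g3_map <- function(traj, r12_window,
                   orientation = orientation_condition("none"),
                   vel = trajectory_velocities(traj),
                   states = NULL, state_filter = NULL,
                   bin = 0.2, extent = 3, domain_radius = NULL) {
  if (n_fish(traj) != 3L) stopf("g3_map needs exactly 3 fish")
  if (traj$ndim != 2L) stopf("g3_map is defined for 2D trajectories")
  stopifnot(length(r12_window) == 2L, r12_window[1] < r12_window[2])
  frames <- state_frames(traj, states, state_filter)
  if (!length(frames)) stopf("no frames pass the state filter")
  pos <- traj$positions
  nb <- as.integer(round(2 * extent / bin))
  counts <- matrix(0, nb, nb)
  n_samp <- 0L
  orderings <- list(c(1, 2, 3), c(2, 1, 3), c(1, 3, 2), c(3, 1, 2),
                    c(2, 3, 1), c(3, 2, 1))
  geom <- list()
  for (ord in orderings) {
    mc <- midframe_coords(pos, frames, ord[1], ord[2], ord[3])
    ok <- !is.na(mc$r12) & mc$r12 >= r12_window[1] & mc$r12 <= r12_window[2] &
      !is.na(mc$x)
    if (orientation$mode != "none") {
      for (fidx in which(ok))
        ok[fidx] <- orientation_filter(traj, vel, frames[fidx],
                                       ord[1], ord[2], orientation)
    }
    if (!any(ok)) next
    xs <- mc$x[ok]; ys <- mc$y[ok]
    if (orientation$mode == "none") {
      # x-mirror symmetrization (counts doubled; n_samples counts
      # physical samples only)
      acc <- accumulate2d(counts, c(xs, -xs), c(ys, ys), -extent, bin, nb)
      counts <- acc$counts
    } else {
      acc <- accumulate2d(counts, xs, ys, -extent, bin, nb)
      counts <- acc$counts
    }
    n_samp <- n_samp + length(xs)
    if (!is.null(domain_radius))
      geom[[length(geom) + 1L]] <-
        cbind(ox = mc$ox[ok], oy = mc$oy[ok], cc = mc$cc[ok], ss = mc$ss[ok])
  }
  if (n_samp == 0L) stopf("no qualifying frames for the g3 map")
  ref <- NULL
  g3src <- counts
  if (!is.null(domain_radius)) {
    gm <- do.call(rbind, geom)
    xc <- seq(-extent + bin / 2, extent - bin / 2, by = bin)
    ref <- matrix(0, nb, nb)
    mirror <- orientation$mode == "none"
    for (i in seq_len(nb)) {
      for (j in seq_len(nb)) {
        lx <- gm[, "ox"] + gm[, "cc"] * xc[i] - gm[, "ss"] * xc[j]
        ly <- gm[, "oy"] + gm[, "ss"] * xc[i] + gm[, "cc"] * xc[j]
        p <- mean(lx^2 + ly^2 <= domain_radius^2)
        if (mirror) {
          lx2 <- gm[, "ox"] - gm[, "cc"] * xc[i] - gm[, "ss"] * xc[j]
          ly2 <- gm[, "oy"] - gm[, "ss"] * xc[i] + gm[, "cc"] * xc[j]
          p <- (p + mean(lx2^2 + ly2^2 <= domain_radius^2)) / 2
        }
        ref[i, j] <- p
      }
    }
    g3src <- ifelse(ref > 0, counts / ref, NA_real_)
  }
  g3 <- g3src / max(g3src, na.rm = TRUE)
  structure(list(xbreaks = seq(-extent, extent, by = bin),
                 ybreaks = seq(-extent, extent, by = bin),
                 counts = counts, ref = ref, g3 = g3, g3k = NULL,
                 r12_window = r12_window, orientation = orientation$mode,
                 n_samples = n_samp,
                 # effectively independent configurations: unordered-pair
                 # symmetrization duplicates every sample in mirror mode
                 n_eff = if (orientation$mode == "none") n_samp / 2 else n_samp,
                 domain_radius = domain_radius),
            class = "triplet_map")
}

#' @export
print.triplet_map <- function(x, ...) {
  cat(sprintf(
    "triplet_map (orientation %s, r12 in [%.3g, %.3g]): %dx%d bins, %d samples%s\n",
    x$orientation, x$r12_window[1], x$r12_window[2], nrow(x$counts),
    ncol(x$counts), x$n_samples,
    if (is.null(x$g3k)) "" else ", Kirkwood side present"))
  invisible(x)
}

#' Kirkwood superposition prediction for a g3 map
#'
#' Predicts the three-body map from the radial pair correlation:
#' `g3K(x, y) ~ g2(|r_13|) g2(|r_23|)` with the reference pair fixed at
#' `(+/- r12/2, 0)` (the `g2(r_12)` factor is constant over the map and
#' removed by max-normalization). `g2` is interpolated linearly between
#' radial bins; bins needing distances outside the estimated range are
#' flagged `NA`.
#'
#' @param radial a [radial_g2()] estimated on the same ensemble and state
#'   filter.
#' @param map a `triplet_map` from [g3_map()] supplying the geometry.
#' @return the `triplet_map` with its `g3k` side filled (max-normalized).
#' @export
kirkwood_map <- function(radial, map) {
  stopifnot(inherits(radial, "radial_g2"), inherits(map, "triplet_map"))
  r12c <- mean(map$r12_window)
  xc <- (map$xbreaks[-1] + map$xbreaks[-length(map$xbreaks)]) / 2
  yc <- (map$ybreaks[-1] + map$ybreaks[-length(map$ybreaks)]) / 2
  g2fun <- function(r) {
    out <- approx(radial$r, radial$g2, xout = r, rule = 1)$y
    out  # NA outside the estimated range -> flagged missing
  }
  gk <- outer(xc, yc, function(x, y) {
    r13 <- sqrt((x + r12c / 2)^2 + y^2)
    r23 <- sqrt((x - r12c / 2)^2 + y^2)
    g2fun(r13) * g2fun(r23)
  })
  mx <- max(gk, na.rm = TRUE)
  if (is.finite(mx) && mx > 0) gk <- gk / mx
  map$g3k <- gk
  map
}

#' Discrepancy between an observed g3 map and its Kirkwood prediction
#'
#' Per-bin difference `g3 - g3K` of the two max-normalized maps, with a
#' summary scalar (maximum absolute difference over interior bins, at
#' least 2 bins from the map edge) and a binomial sampling envelope.
#' Two envelopes are reported: a per-bin one (the standard deviation of
#' the normalized observed intensity when the true bin probabilities are
#' those implied by the Kirkwood side) and, when `n_boot > 0`, a
#' parametric-bootstrap null envelope `null_max_abs`: the mean of the
#' summary scalar over synthetic maps whose counts are drawn from the
#' binomial (multinomial) law implied by the Kirkwood side. The
#' bootstrap envelope also absorbs the bias that max-normalizing a noisy
#' histogram introduces, which the per-bin envelope cannot see; an
#' observed `max_abs` within a small multiple of `null_max_abs` is
#' indistinguishable from sampling noise. Also reports whether the
#' central region (the third fish between the reference pair:
#' `|x| <= r12/2`, `|y| <= 0.5`) exceeds the prediction.
#'
#' @param map a `triplet_map` with both sides present (see
#'   [kirkwood_map()]).
#' @param n_boot number of bootstrap null maps (default 100; 0 skips).
#'   Uses the current RNG stream; seed for reproducibility.
#' @return list of class `kirkwood_discrepancy`: `diff` (matrix),
#'   `envelope` (matrix of per-bin binomial standard deviations),
#'   `max_abs` (summary scalar), `max_envelope`, `null_max_abs`,
#'   `interior` (logical mask), `central_excess` (mean central-region
#'   difference), `central_exceeds` (logical: central excess beyond 3
#'   per-bin envelopes).
#' @export
kirkwood_discrepancy <- function(map, n_boot = 100) {
  stopifnot(inherits(map, "triplet_map"))
  if (is.null(map$g3k)) stopf("Kirkwood side missing; run kirkwood_map() first")
  if (!identical(dim(map$g3), dim(map$g3k))) stopf("mismatched binning")
  d <- map$g3 - map$g3k
  nb <- nrow(d)
  interior <- matrix(FALSE, nb, nb)
  interior[3:(nb - 2), 3:(nb - 2)] <- TRUE
  interior[is.na(d)] <- FALSE
  # expected counts under the Kirkwood prediction (times the edge
  # reference, if any), scaled to the total observed count
  ref <- map$ref %||% matrix(1, nb, nb)
  usable <- !is.na(map$g3k) & ref > 0
  tot <- sum(map$counts[usable])
  n_eff <- map$n_eff %||% tot
  pk <- map$g3k * ref
  pk <- pk / sum(pk[usable])
  # per-bin envelope on the scale of the normalized intensity:
  # sd(counts_bin) / (ref_bin * M), with M the observed normalizer and
  # count variance at the effective (deduplicated) sample size
  M <- max(ifelse(ref > 0, map$counts / ref, NA_real_), na.rm = TRUE)
  env <- sqrt(pk * pmax(1 - pk, 0) / n_eff) * tot / (ref * M)
  env[!usable] <- NA_real_
  max_abs <- max(abs(d[interior]), na.rm = TRUE)
  max_env <- max(env[interior], na.rm = TRUE)
  null_max_abs <- NA_real_
  if (n_boot > 0) {
    pkv <- pk[usable]
    scale_up <- tot / n_eff
    stat <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      cb <- matrix(0, nb, nb)
      cb[usable] <- stats::rmultinom(1, round(n_eff), pkv) * scale_up
      gb <- ifelse(ref > 0, cb / ref, NA_real_)
      gb <- gb / max(gb[usable])
      db <- gb - map$g3k
      stat[b] <- max(abs(db[interior]), na.rm = TRUE)
    }
    null_max_abs <- mean(stat)
  }
  xc <- (map$xbreaks[-1] + map$xbreaks[-length(map$xbreaks)]) / 2
  yc <- (map$ybreaks[-1] + map$ybreaks[-length(map$ybreaks)]) / 2
  central <- outer(abs(xc) <= mean(map$r12_window) / 2, abs(yc) <= 0.5, `&`) &
    !is.na(d)
  central_excess <- if (any(central)) mean(d[central]) else NA_real_
  central_exceeds <- isTRUE(central_excess >
                              3 * mean(env[central], na.rm = TRUE))
  structure(list(diff = d, envelope = env, max_abs = max_abs,
                 max_envelope = max_env, null_max_abs = null_max_abs,
                 interior = interior,
                 central_excess = central_excess,
                 central_exceeds = central_exceeds),
            class = "kirkwood_discrepancy")
}

#' @export
print.kirkwood_discrepancy <- function(x, ...) {
  cat(sprintf(
    "kirkwood_discrepancy: max |g3 - g3K| = %.4f on interior bins (max envelope %.4f)\n",
    x$max_abs, x$max_envelope))
  cat(sprintf("  central region: mean excess %+.4f%s\n", x$central_excess,
              if (x$central_exceeds) " (exceeds 3 envelopes)" else ""))
  invisible(x)
}
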