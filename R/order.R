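#' State classification thresholds
#'
#' Frame-by-frame thresholds on the order parameters: schooling when the
#' polarization exceeds `high`, milling when the rotation exceeds `high`,
#' swarming when both are below `low`.
#'
#' @param high upper threshold (default 0.65).
#' @param low lower threshold (default 0.35).
#' @return an object of class `state_thresholds`.
#' @export
state_thresholds <- function(high = 0.65, low = 0.35) {
  if (!(0 <= low && low < high && high <= 1))
    stopf("need 0 <= low < high <= 1")
  structure(list(high = high, low = low), class = "state_thresholds")
}

shoal_states <- c("schooling", "milling", "swarming", "unclassified")

#' Polarization order parameter of one frame
#'
#' `O_p = |sum_i v_i / |v_i|| / N` over the fish with defined headings:
#' 1 when all fish swim in the same direction, near 0 for random
#' directions.
#'
#' @param v numeric `n x d` matrix of velocities (d = 2 or 3), one row per
#'   fish. Rows with `NA` or speed below `speed_floor` are dropped.
#' @param speed_floor minimum speed for a defined heading.
#' @return `O_p` in `[0, 1]`; `NA` if no fish has a defined heading.
#' @export
polarization <- function(v, speed_floor = 1e-6) {
  v <- as.matrix(v)
  sp <- sqrt(rowSums(v^2))
  ok <- !is.na(sp) & sp >= speed_floor
  if (!any(ok)) return(NA_real_)
  u <- v[ok, , drop = FALSE] / sp[ok]
  sqrt(sum(colSums(u)^2)) / sum(ok)
}

#' Rotation order parameter of one frame
#'
#' `O_r = |sum_i vhat_i x uhat_i| / N` with `uhat_i` the unit vector from
#' the group center of mass to fish i: 1 when all fish rotate about the
#' center with the same handedness. In 2D the cross product is the scalar
#' z-component; in 3D the vector norm of the summed cross products is
#' taken.
#'
#' @param r numeric `n x d` positions; `v` matching velocities.
#' @inheritParams polarization
#' @param center optional center to use instead of the centroid of the
#'   participating fish (used for subgroup analysis).
#' @return `O_r` in `[0, 1]`; `NA` if fewer than 2 fish participate. A
#'   fish exactly at the center is excluded.
#' @export
rotation <- function(r, v, speed_floor = 1e-6, center = NULL) {
  r <- as.matrix(r); v <- as.matrix(v)
  sp <- sqrt(rowSums(v^2))
  ok <- !is.na(sp) & sp >= speed_floor & stats::complete.cases(r)
  if (sum(ok) < 2) return(NA_real_)
  r <- r[ok, , drop = FALSE]
  v <- v[ok, , drop = FALSE] / sp[ok]
  cm <- center %||% colMeans(r)
  u <- sweep(r, 2, cm)
  du <- sqrt(rowSums(u^2))
  keep <- du > 1e-12
  if (sum(keep) < 2) return(NA_real_)
  u <- u[keep, , drop = FALSE] / du[keep]
  v <- v[keep, , drop = FALSE]
  n <- sum(ok)  # N counts all fish with defined headings
  if (ncol(r) == 2) {
    abs(sum(v[, 1] * u[, 2] - v[, 2] * u[, 1])) / n
  } else {
    cx <- v[, 2] * u[, 3] - v[, 3] * u[, 2]
    cy <- v[, 3] * u[, 1] - v[, 1] * u[, 3]
    cz <- v[, 1] * u[, 2] - v[, 2] * u[, 1]
    sqrt(sum(cx)^2 + sum(cy)^2 + sum(cz)^2) / n
  }
}

#' Classify a frame into schooling / milling / swarming
#'
#' Schooling if `O_p > high`; milling if `O_r > high`; swarming if both
#' `< low`; otherwise unclassified. If both exceed `high` (a region the
#' thresholds leave ambiguous) the larger order parameter wins; an exact
#' tie is unclassified. Vectorized over frames.
#'
#' @param op,orr polarization and rotation values in `[0, 1]` (NA allowed).
#' @param thresholds a [state_thresholds()].
#' @return factor with levels schooling, milling, swarming, unclassified
#'   (`NA` where an order parameter is undefined).
#' @export
classify_state <- function(op, orr, thresholds = state_thresholds()) {
  hi <- thresholds$high; lo <- thresholds$low
  out <- rep(NA_character_, length(op))
  valid <- !is.na(op) & !is.na(orr)
  out[valid] <- "unclassified"
  out[valid & op > hi & orr <= hi] <- "schooling"
  out[valid & orr > hi & op <= hi] <- "milling"
  both <- valid & op > hi & orr > hi
  out[both & op > orr] <- "schooling"
  out[both & orr > op] <- "milling"
  out[valid & op < lo & orr < lo] <- "swarming"
  factor(out, levels = shoal_states)
}

#' Per-frame order parameters and state labels
#'
#' Computes `O_p`, `O_r` and the state label for every frame of a
#' trajectory. Fish with undefined headings (missing sample or speed
#' below the floor) are excluded from that frame's sums; `N` is the count
#' of participating fish.
#'
#' @param traj a [fish_trajectory()].
#' @param vel a `fish_velocity`; default [trajectory_velocities()].
#' @param thresholds a [state_thresholds()].
#' @param speed_floor heading floor (L/T).
#' @return a data.frame of class `order_series` with columns `frame`,
#'   `O_p`, `O_r`, `n_used`, `state`.
#' @export
order_parameters <- function(traj, vel = trajectory_velocities(traj, speed_floor),
                             thresholds = state_thresholds(),
                             speed_floor = 1e-6) {
  stopifnot(inherits(traj, "fish_trajectory"), inherits(vel, "fish_velocity"))
  v <- vel$v
  nf <- dim(v)[1L]; np <- dim(v)[2L]; nd <- dim(v)[3L]
  if (nf != n_frames(traj)) stopf("velocity series does not match trajectory")
  sp <- sqrt(apply(v^2, c(1L, 2L), sum))
  def <- !is.na(sp) & sp >= speed_floor & !apply(is.na(traj$positions),
                                                 c(1L, 2L), any)
  dim(def) <- c(nf, np)
  nuse <- rowSums(def)
  slice <- function(a, k) { m <- a[, , k]; dim(m) <- c(nf, np); m }
  # unit headings, NA where undefined
  u <- v
  for (k in seq_len(nd)) u[, , k] <- ifelse(def, slice(v, k) / sp, NA_real_)
  op <- sqrt(Reduce(`+`, lapply(seq_len(nd), function(k)
    rowSums(slice(u, k), na.rm = TRUE)^2))) / nuse
  # center of mass over participating fish
  pos <- traj$positions
  rel <- pos
  for (k in seq_len(nd)) {
    pk <- ifelse(def, pos[, , k], NA_real_)
    dim(pk) <- c(nf, np)
    cmk <- rowMeans(pk, na.rm = TRUE)
    rel[, , k] <- pk - cmk
  }
  dr <- sqrt(apply(rel^2, c(1L, 2L), sum))
  dr[dr <= 1e-12] <- NA_real_  # fish at the center are excluded
  if (nd == 2L) {
    cz <- slice(u, 1) * (slice(rel, 2) / dr) -
      slice(u, 2) * (slice(rel, 1) / dr)
    orr <- abs(rowSums(cz, na.rm = TRUE)) / nuse
  } else {
    uh <- lapply(1:3, function(k) slice(rel, k) / dr)
    vv <- lapply(1:3, function(k) slice(u, k))
    cx <- rowSums(vv[[2]] * uh[[3]] - vv[[3]] * uh[[2]], na.rm = TRUE)
    cy <- rowSums(vv[[3]] * uh[[1]] - vv[[1]] * uh[[3]], na.rm = TRUE)
    cz <- rowSums(vv[[1]] * uh[[2]] - vv[[2]] * uh[[1]], na.rm = TRUE)
    orr <- sqrt(cx^2 + cy^2 + cz^2) / nuse
  }
  op[nuse == 0L] <- NA_real_
  orr[nuse < 2L] <- NA_real_
  out <- data.frame(frame = traj$frames, O_p = op, O_r = orr,
                    n_used = nuse,
                    state = classify_state(op, orr, thresholds))
  attr(out, "thresholds") <- thresholds
  class(out) <- c("order_series", "data.frame")
  out
}

#' State occupancy of an order-parameter series
#'
#' Fraction of classified frames spent in each state.
#'
#' @param series an `order_series` (or any data.frame with a `state`
#'   column), e.g. from [order_parameters()] or [subgroup_series()].
#' @return data.frame of class `occupancy_report` with columns `state`,
#'   `frames`, `fraction`; attribute `n_total` counts frames with a
#'   defined label. Fractions sum to 1.
#' @export
occupancy <- function(series) {
  st <- series$state
  if (is.null(st)) stopf("input has no state column")
  st <- st[!is.na(st)]
  if (!length(st)) stopf("no classified frames")
  tab <- table(factor(st, levels = shoal_states))
  out <- data.frame(state = names(tab), frames = as.integer(tab),
                    fraction = as.numeric(tab) / length(st))
  attr(out, "n_total") <- length(st)
  class(out) <- c("occupancy_report", "data.frame")
  out
}

#' 2D histogram of (O_p, O_r) values
#'
#' Density of the joint order-parameter distribution on the unit square,
#' the standard visualization of multistability. The default bin side of
#' 0.025 gives a 40 x 40 grid.
#'
#' @param series an `order_series`.
#' @param bin_side bin width on both axes.
#' @return list of class `op_or_density`: `op_breaks`, `or_breaks`,
#'   `counts` (O_p along rows), `n_frames`.
#' @export
op_or_density <- function(series, bin_side = 0.025) {
  nb <- ceiling(1 / bin_side)
  br <- seq(0, by = bin_side, length.out = nb + 1L)
  ok <- !is.na(series$O_p) & !is.na(series$O_r)
  i <- pmin(floor(series$O_p[ok] / bin_side) + 1L, nb)
  j <- pmin(floor(series$O_r[ok] / bin_side) + 1L, nb)
  counts <- matrix(0L, nb, nb)
  t1 <- table(factor(i + (j - 1L) * nb, levels = seq_len(nb * nb)))
  counts[] <- as.integer(t1)
  structure(list(op_breaks = br, or_breaks = br, counts = counts,
                 n_frames = sum(ok)),
            class = "op_or_density")
}

#' Nearest-neighbor subgroup order parameters
#'
#' For every frame and every focal fish, forms the subgroup of the focal
#' fish plus its `n - 1` nearest neighbors (Euclidean distance at that
#' frame, ties broken by fish id) and evaluates `O_p` and `O_r` within the
#' subgroup, using the subgroup's own center of mass.
#'
#' @param traj a [fish_trajectory()] with at least `n` fish.
#' @param n subgroup size, `2 <= n <= N`.
#' @param vel velocity series (default [trajectory_velocities()]).
#' @param thresholds a [state_thresholds()].
#' @param speed_floor heading floor.
#' @return data.frame of class `c("subgroup_series", "order_series")` with
#'   columns `frame`, `focal`, `O_p`, `O_r`, `n_used`, `state`.
#' @export
subgroup_series <- function(traj, n, vel = trajectory_velocities(traj, speed_floor),
                            thresholds = state_thresholds(),
                            speed_floor = 1e-6) {
  stopifnot(inherits(traj, "fish_trajectory"))
  np <- n_fish(traj)
  if (n < 2 || n > np) stopf("need 2 <= n <= %d", np)
  nf <- n_frames(traj)
  pos <- traj$positions
  v <- vel$v
  res <- vector("list", nf)
  for (f in seq_len(nf)) {
    p <- pos[f, , , drop = TRUE]
    if (np == 1L) p <- matrix(p, nrow = 1L)
    vv <- v[f, , , drop = TRUE]
    present <- stats::complete.cases(p)
    dmat <- as.matrix(stats::dist(p))
    opv <- orv <- rep(NA_real_, np)
    nuv <- integer(np)
    for (i in seq_len(np)) {
      if (!present[i]) next
      d <- dmat[i, ]
      d[!present] <- Inf
      ord <- order(d, seq_len(np))  # ties broken by fish id
      grp <- ord[seq_len(min(n, sum(present)))]
      if (length(grp) < n) next
      opv[i] <- polarization(vv[grp, , drop = FALSE], speed_floor)
      orv[i] <- rotation(p[grp, , drop = FALSE], vv[grp, , drop = FALSE],
                         speed_floor)
      nuv[i] <- length(grp)
    }
    res[[f]] <- data.frame(frame = traj$frames[f], focal = traj$ids,
                           O_p = opv, O_r = orv, n_used = nuv)
  }
  out <- do.call(rbind, res)
  out$state <- classify_state(out$O_p, out$O_r, thresholds)
  out <- out[!is.na(out$O_p) | !is.na(out$O_r), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- thresholds
  attr(out, "subgroup_n") <- n
  class(out) <- c("subgroup_series", "order_series", "data.frame")
  out
}
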