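#' Trajectory container for a group of fish
#'
#' A `fish_trajectory` stores per-frame, per-fish positions in body-length
#' units L, together with the time base. Positions are held in a numeric
#' array with dimensions `(frame, fish, coordinate)`; a missing sample
#' (fish not tracked in a frame) is encoded as `NA` in all coordinates of
#' that `(frame, fish)` slot.
#'
#' @param positions numeric array `(n_frames, n_fish, 2 or 3)`, coordinates
#'   in body lengths.
#' @param frames integer frame indices, strictly increasing. Default
#'   `1:n_frames`.
#' @param ids fish identifiers (coerced to character). Default `1:n_fish`.
#' @param frame_interval seconds between consecutive frames.
#' @param body_length_mm physical size of the length unit L in mm.
#' @param time_unit_s seconds per time unit T (velocities are reported in
#'   L per T).
#' @param velocities optional analytic velocity sidecar: numeric array of
#'   the same shape as `positions`, in L per T. When present it is used by
#'   [trajectory_velocities()] instead of finite differences.
#' @return an object of class `fish_trajectory`.
#' @seealso [read_trajectory()], [estimate_velocities()]
#' @export
fish_trajectory <- function(positions, frames = NULL, ids = NULL,
                            frame_interval = 0.3, body_length_mm = 30,
                            time_unit_s = 0.3, velocities = NULL) {
  if (!is.array(positions) || length(dim(positions)) != 3L)
    stopf("positions must be a 3-d array (frame, fish, coordinate)")
  nd <- dim(positions)[3L]
  if (!nd %in% c(2L, 3L))
    stopf("positions must have 2 or 3 coordinates, got %d", nd)
  nf <- dim(positions)[1L]
  np <- dim(positions)[2L]
  frames <- as.integer(frames %||% seq_len(nf))
  ids <- as.character(ids %||% seq_len(np))
  if (length(frames) != nf) stopf("length(frames) != n_frames")
  if (length(ids) != np) stopf("length(ids) != n_fish")
  if (nf > 1L && any(diff(frames) <= 0L))
    stopf("frame indices must be strictly increasing")
  if (anyDuplicated(ids)) stopf("fish ids must be unique")
  if (!is.numeric(body_length_mm) || body_length_mm <= 0)
    stopf("body_length_mm must be > 0")
  if (frame_interval <= 0) stopf("frame_interval must be > 0")
  bad <- is.infinite(positions) | is.nan(positions)
  if (any(bad)) stopf("positions must be finite or NA")
  # missing samples must be masked consistently across coordinates
  na2 <- apply(is.na(positions), c(1L, 2L), any)
  naall <- apply(is.na(positions), c(1L, 2L), all)
  if (any(na2 != naall))
    stopf("a (frame, fish) sample must be NA in all coordinates or none")
  if (!is.null(velocities)) {
    if (!identical(dim(velocities), dim(positions)))
      stopf("velocity sidecar must match the shape of positions")
  }
  dimnames(positions) <- list(NULL, ids, c("x", "y", "z")[seq_len(nd)])
  structure(
    list(positions = positions, frames = frames, ids = ids,
         frame_interval = frame_interval, body_length_mm = body_length_mm,
         time_unit_s = time_unit_s, ndim = nd, velocities = velocities),
    class = "fish_trajectory")
}

#' @export
print.fish_trajectory <- function(x, ...) {
  cat(sprintf(
    "fish_trajectory: %d fish, %d frames, %dD\n", length(x$ids),
    length(x$frames), x$ndim))
  cat(sprintf("  frame interval %.4g s, body length %.4g mm (1 L), T = %.4g s\n",
              x$frame_interval, x$body_length_mm, x$time_unit_s))
  nmiss <- sum(apply(is.na(x$positions), c(1, 2), all))
  if (nmiss > 0) cat(sprintf("  %d missing (frame, fish) samples\n", nmiss))
  if (!is.null(x$velocities)) cat("  analytic velocity sidecar present\n")
  invisible(x)
}

#' Number of fish / frames in a trajectory
#' @param traj a [fish_trajectory()].
#' @return integer count.
#' @export
n_fish <- function(traj) length(traj$ids)

#' @rdname n_fish
#' @export
n_frames <- function(traj) length(traj$frames)

#' Read a trajectory from a delimited text file
#'
#' The file must be comma-separated with a header naming `frame`, `id`,
#' `x`, `y` and optionally `z` columns. Missing samples may be encoded as
#' empty fields. Coordinates default to body-length units; set
#' `unit = "mm"` to convert on input.
#'
#' @param path file path.
#' @param frame_interval seconds between consecutive frames (required: the
#'   file stores no time base).
#' @param body_length_mm physical body length in mm (default 30).
#' @param unit `"bodylength"` (no conversion) or `"mm"` (divide by
#'   `body_length_mm`).
#' @param time_unit_s seconds per time unit T.
#' @return a [fish_trajectory()].
#' @export
read_trajectory <- function(path, frame_interval = 0.3, body_length_mm = 30,
                            unit = c("bodylength", "mm"), time_unit_s = 0.3) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- read.csv(path, colClasses = "character", comment.char = "#",
                 strip.white = TRUE)
  need <- c("frame", "id", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("missing column(s) in %s: %s", path, paste(miss, collapse = ", "))
  has_z <- "z" %in% names(df)
  nd <- if (has_z) 3L else 2L

  parse_num <- function(col, name, allow_empty = FALSE) {
    v <- df[[col]]
    empty <- !nzchar(v)
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !empty)
    if (length(bad))
      stopf("unparseable %s value '%s' at data row %d of %s",
            name, v[bad[1]], bad[1], path)
    if (!allow_empty && any(empty))
      stopf("empty %s field at data row %d of %s", name, which(empty)[1], path)
    out
  }
  frame <- parse_num("frame", "frame")
  id <- df[["id"]]
  key <- paste(frame, id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("duplicate (frame, id) = (%s, %s) at data row %d of %s",
          frame[dup[1]], id[dup[1]], dup[1], path)
  coords <- lapply(c("x", "y", if (has_z) "z"), function(cn)
    parse_num(cn, cn, allow_empty = TRUE))
  # partial missing (some coordinates empty) is invalid
  nmat <- vapply(coords, is.na, logical(nrow(df)))
  if (nrow(df) == 1L) nmat <- matrix(nmat, nrow = 1L)
  partial <- which(apply(nmat, 1L, function(r) any(r) && !all(r)))
  if (length(partial))
    stopf("sample at data row %d of %s is missing only some coordinates",
          partial[1], path)

  frames <- sort(unique(as.integer(frame)))
  ids <- unique(id)
  pos <- array(NA_real_, c(length(frames), length(ids), nd))
  fi <- match(as.integer(frame), frames)
  pi_ <- match(id, ids)
  for (k in seq_len(nd)) pos[cbind(fi, pi_, k)] <- coords[[k]]
  if (unit == "mm") pos <- pos / body_length_mm
  shoal_log("read_trajectory", path = path, n_fish = length(ids),
            n_frames = length(frames))
  fish_trajectory(pos, frames = frames, ids = ids,
                  frame_interval = frame_interval,
                  body_length_mm = body_length_mm, time_unit_s = time_unit_s)
}

#' Write a trajectory to a delimited text file
#'
#' Writes the standard `frame,id,x,y[,z]` CSV dialect in body-length units;
#' missing samples become empty fields. The file round-trips through
#' [read_trajectory()] with bit-identical frame/id columns and coordinates
#' equal to formatting precision (12 significant digits).
#'
#' @param traj a [fish_trajectory()].
#' @param path output file path.
#' @param velocity_path optional path for an analytic velocity sidecar CSV
#'   (written only if the trajectory carries one).
#' @return `invisible(path)`.
#' @export
write_trajectory <- function(traj, path, velocity_path = NULL) {
  stopifnot(inherits(traj, "fish_trajectory"))
  fmt_arr <- function(a) {
    nf <- dim(a)[1L]; np <- dim(a)[2L]; nd <- dim(a)[3L]
    df <- data.frame(
      frame = rep(traj$frames, each = np),
      id = rep(traj$ids, times = nf))
    for (k in seq_len(nd)) {
      v <- as.vector(t(a[, , k, drop = TRUE]))
      if (nf == 1L) v <- a[1L, , k]
      df[[c("x", "y", "z")[k]]] <- ifelse(is.na(v), "", sprintf("%.12g", v))
    }
    df
  }
  df <- fmt_arr(traj$positions)
  # drop rows that are fully missing? keep them: an explicit mask row
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: body length L = %g mm, T = %g s",
                     traj$body_length_mm, traj$time_unit_s), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  if (!is.null(velocity_path) && !is.null(traj$velocities)) {
    dfv <- fmt_arr(traj$velocities)
    write.csv(dfv, velocity_path, row.names = FALSE, quote = FALSE)
  }
  shoal_log("write_trajectory", path = path, rows = nrow(df))
  invisible(path)
}

#' Estimate velocities by finite differences
#'
#' Central differences at interior frames,
#' `v(t) = (r(t+1) - r(t-1)) / (2 dt)`, one-sided differences at the two
#' edge frames (flagged). Velocities are reported in L per time unit T.
#' A fish whose speed falls below `speed_floor` has an undefined heading
#' and is flagged as undefined for heading-dependent observables.
#'
#' @param traj a [fish_trajectory()] with at least 2 frames.
#' @param speed_floor minimum speed (L/T) for a heading to count as
#'   defined. Default `1e-6`.
#' @return an object of class `fish_velocity`: list with `v` (array shaped
#'   like the positions, L/T), `defined` (logical `(frame, fish)` matrix),
#'   `edge` (logical per frame, one-sided scheme), `scheme`, `speed_floor`.
#' @export
estimate_velocities <- function(traj, speed_floor = 1e-6) {
  stopifnot(inherits(traj, "fish_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2L) stopf("need at least 2 frames to estimate velocities")
  dt_T <- diff(traj$frames) * traj$frame_interval / traj$time_unit_s
  pos <- traj$positions
  v <- array(NA_real_, dim(pos))
  edge <- logical(nf)
  if (nf == 2L) {
    v[1L, , ] <- (pos[2L, , ] - pos[1L, , ]) / dt_T[1L]
    v[2L, , ] <- v[1L, , ]
    edge[] <- TRUE
  } else {
    i <- 2:(nf - 1L)
    span <- dt_T[i] + dt_T[i - 1L]
    v[i, , ] <- (pos[i + 1L, , , drop = FALSE] -
                   pos[i - 1L, , , drop = FALSE]) / span
    v[1L, , ] <- (pos[2L, , ] - pos[1L, , ]) / dt_T[1L]
    v[nf, , ] <- (pos[nf, , ] - pos[nf - 1L, , ]) / dt_T[nf - 1L]
    edge[c(1L, nf)] <- TRUE
  }
  new_fish_velocity(v, traj, scheme = "central", edge = edge,
                    speed_floor = speed_floor)
}

new_fish_velocity <- function(v, traj, scheme, edge = NULL,
                              speed_floor = 1e-6) {
  nf <- dim(v)[1L]
  speed <- sqrt(apply(v^2, c(1L, 2L), sum))
  defined <- !is.na(speed) & speed >= speed_floor
  dim(defined) <- c(nf, dim(v)[2L])
  structure(
    list(v = v, defined = defined, edge = edge %||% logical(nf),
         scheme = scheme, speed_floor = speed_floor),
    class = "fish_velocity")
}

#' @export
print.fish_velocity <- function(x, ...) {
  cat(sprintf("fish_velocity (%s scheme): %d frames x %d fish; %d undefined headings\n",
              x$scheme, dim(x$v)[1], dim(x$v)[2], sum(!x$defined)))
  invisible(x)
}

#' Velocities for a trajectory, preferring an analytic sidecar
#'
#' Fixture generators and the simulator attach exact velocities to the
#' trajectories they produce; this accessor returns those when present and
#' falls back to [estimate_velocities()] otherwise.
#'
#' @inheritParams estimate_velocities
#' @return a `fish_velocity` object.
#' @export
trajectory_velocities <- function(traj, speed_floor = 1e-6) {
  stopifnot(inherits(traj, "fish_trajectory"))
  if (!is.null(traj$velocities))
    return(new_fish_velocity(traj$velocities, traj, scheme = "analytic",
                             speed_floor = speed_floor))
  estimate_velocities(traj, speed_floor = speed_floor)
}
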