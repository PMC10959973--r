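test_that("bond angles match brute force and sum to 180 per triangle", {
  tr <- ideal_gas_frames(3, region_radius = 3, n_frames = 300, seed = 8)
  w <- c(0, 10)  # window wide enough to accept every triangle
  ba <- bond_angles(tr, w, bin_width = 5)
  # independent brute-force resampling of the same frames
  cnt <- numeric(36)
  for (f in seq_len(300)) {
    p <- tr$positions[f, , ]
    angs <- sapply(1:3, function(i) {
      o <- setdiff(1:3, i)
      a <- p[o[1], ] - p[i, ]; b <- p[o[2], ] - p[i, ]
      acos(max(min(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), 1), -1)) * 180 / pi
    })
    expect_equal(sum(angs), 180, tolerance = 1e-9)
    bi <- pmin(floor(angs / 5) + 1, 36)
    for (b in bi) cnt[b] <- cnt[b] + 1
  }
  expect_equal(ba$prob, cnt / sum(cnt), tolerance = 1e-12)
  expect_equal(sum(ba$prob), 1)
  expect_error(bond_angles(perfect_school(4, n_frames = 2), w), "exactly 3")
})

test_that("orientation conditions discriminate pair geometries", {
  mk <- function(h1, h2, sep) {
    pos <- array(0, c(1, 2, 2)); pos[1, 2, ] <- sep
    vel <- array(0, c(1, 2, 2))
    vel[1, 1, ] <- c(cos(h1), sin(h1)); vel[1, 2, ] <- c(cos(h2), sin(h2))
    fish_trajectory(pos, velocities = vel)
  }
  side <- orientation_condition("side_by_side")
  tail_ <- orientation_condition("head_to_tail")
  # parallel headings, separation perpendicular: side-by-side only
  tr <- mk(0, 0, c(0, 1.5))
  v <- trajectory_velocities(tr)
  expect_true(orientation_filter(tr, v, 1, 1, 2, side))
  expect_false(orientation_filter(tr, v, 1, 1, 2, tail_))
  # parallel headings, separation along the heading: head-to-tail only
  tr <- mk(0, 0, c(1.5, 0))
  v <- trajectory_velocities(tr)
  expect_false(orientation_filter(tr, v, 1, 1, 2, side))
  expect_true(orientation_filter(tr, v, 1, 1, 2, tail_))
  # antiparallel headings fail both at default thresholds
  tr <- mk(0, pi, c(0, 1.5))
  v <- trajectory_velocities(tr)
  expect_false(orientation_filter(tr, v, 1, 1, 2, side))
  expect_false(orientation_filter(tr, v, 1, 1, 2, tail_))
  expect_error(orientation_condition("side_by_side", heading_tol = 95),
               "thresholds")
})

test_that("g3 maps place the third fish by exact geometry", {
  # third fish pinned at the midpoint: one central bin
  pos <- array(0, c(10, 3, 2))
  pos[, 1, 1] <- -1; pos[, 2, 1] <- 1  # pair along x, r12 = 2
  tr <- fish_trajectory(pos)
  tm <- g3_map(tr, r12_window = c(1.9, 2.1), bin = 0.5, extent = 2)
  occ <- which(tm$counts > 0, arr.ind = TRUE)
  xc <- (tm$xbreaks[-1] + tm$xbreaks[-length(tm$xbreaks)]) / 2
  expect_true(all(abs(xc[occ[, 1]]) < 0.5 & abs(xc[occ[, 2]]) < 0.5))
  # equilateral frames: mass at (0, +/- sqrt(3)/2 * r12)
  trm <- perfect_mill(3, radius = 2, n_frames = 8)
  d <- 2 * 2 * sin(pi / 3)
  tmm <- g3_map(trm, r12_window = c(d - 0.1, d + 0.1), bin = 0.25, extent = 4)
  occm <- which(tmm$counts > 0, arr.ind = TRUE)
  yc <- (tmm$ybreaks[-1] + tmm$ybreaks[-length(tmm$ybreaks)]) / 2
  expect_true(all(abs(abs(yc[occm[, 2]]) - sqrt(3) / 2 * d) < 0.3))
  # unconditioned maps are x-mirror symmetric by construction
  trr <- ideal_gas_frames(3, region_radius = 3, n_frames = 500, seed = 2)
  tmr <- g3_map(trr, r12_window = c(1, 2), bin = 0.5, extent = 3)
  expect_equal(tmr$counts, tmr$counts[nrow(tmr$counts):1, ])
})

test_that("Kirkwood predictions follow the g2 geometry", {
  # flat g2 -> flat g3K
  flat <- data.frame(r = seq(0.125, 9.875, by = 0.25), g2 = 1)
  attr(flat, "r_max") <- 1; class(flat) <- c("radial_g2", "data.frame")
  tm <- g3_map(perfect_mill(3, radius = 2, n_frames = 4),
               r12_window = c(3.3, 3.6), bin = 0.5, extent = 2)
  tmk <- kirkwood_map(flat, tm)
  expect_true(all(abs(tmk$g3k - 1) < 1e-12))
  # near-delta g2 at r0: support concentrates where both pair distances
  # are r0 -- the two intersection points of circles about the ref pair
  r0 <- 2
  g <- exp(-((flat$r - r0) / 0.05)^2)
  delta <- data.frame(r = flat$r, g2 = g / max(g))
  attr(delta, "r_max") <- r0; class(delta) <- c("radial_g2", "data.frame")
  pos <- array(0, c(4, 3, 2))
  pos[, 1, 1] <- -1; pos[, 2, 1] <- 1; pos[, 3, 2] <- sqrt(3)
  tm2 <- g3_map(fish_trajectory(pos), r12_window = c(1.9, 2.1),
                bin = 0.25, extent = 3)
  tm2k <- kirkwood_map(delta, tm2)
  top <- which(tm2k$g3k > 0.5, arr.ind = TRUE)
  xc <- (tm2k$xbreaks[-1] + tm2k$xbreaks[-length(tm2k$xbreaks)]) / 2
  yc <- (tm2k$ybreaks[-1] + tm2k$ybreaks[-length(tm2k$ybreaks)]) / 2
  # expected intersections: (0, +/- sqrt(r0^2 - 1))
  expect_true(all(abs(xc[top[, 1]]) < 0.5))
  expect_true(all(abs(abs(yc[top[, 2]]) - sqrt(r0^2 - 1)) < 0.5))
})

test_that("the discrepancy is zero for identical maps and flags excess", {
  tm <- g3_map(ideal_gas_frames(3, region_radius = 3, n_frames = 2000,
                                seed = 5),
               r12_window = c(1, 2), bin = 0.5, extent = 3)
  tm$g3k <- tm$g3
  kd <- kirkwood_discrepancy(tm, n_boot = 0)
  expect_equal(kd$max_abs, 0)
  # a constructed central observed excess (Kirkwood side lowered in the
  # between-the-pair region) is flagged
  xc <- (tm$xbreaks[-1] + tm$xbreaks[-length(tm$xbreaks)]) / 2
  central <- outer(abs(xc) <= 0.75, abs(xc) <= 0.5, `&`)
  tm2 <- tm
  tm2$g3k[central] <- pmax(tm2$g3[central] - 0.5, 0)
  kd2 <- kirkwood_discrepancy(tm2, n_boot = 0)
  expect_gt(kd2$central_excess, 0.3)
  expect_true(kd2$central_exceeds)
  tm3 <- tm; tm3$g3k <- NULL
  expect_error(kirkwood_discrepancy(tm3), "Kirkwood side missing")
})

test_that("the ideal-gas Kirkwood null passes at modest sample size", {
  tr <- ideal_gas_frames(3, region_radius = 5, n_frames = 2e4, seed = 19)
  rg <- radial_g2(tr, bin = 0.25, r_range = c(0, 10), domain_radius = 5)
  tm <- g3_map(tr, r12_window = c(1.5, 2), bin = 0.5, extent = 3,
               domain_radius = 5)
  tm <- kirkwood_map(rg, tm)
  set.seed(100)
  kd <- kirkwood_discrepancy(tm)
  expect_lt(kd$max_abs, 3 * kd$null_max_abs)
})
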