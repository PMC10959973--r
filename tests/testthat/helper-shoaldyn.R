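# shared helpers for the test suite

# a small trajectory with irregular motion, used for round-trip and
# oracle tests
toy_trajectory <- function(n = 3, n_frames = 20, seed = 42, missing = 0) {
  set.seed(seed)
  pos <- array(rnorm(n_frames * n * 2, sd = 3), c(n_frames, n, 2))
  # smooth it so finite-difference headings are defined
  for (k in 1:2) pos[, , k] <- apply(pos[, , k, drop = FALSE], 2, cumsum)
  if (missing > 0) {
    idx <- cbind(sample(n_frames, missing, replace = TRUE),
                 sample(n, missing, replace = TRUE))
    for (r in seq_len(missing)) pos[idx[r, 1], idx[r, 2], ] <- NA
  }
  fish_trajectory(pos)
}

# independent brute-force evaluation of the rotation order parameter,
# term by term
rotation_bruteforce <- function(r, v) {
  n <- nrow(r)
  cm <- colMeans(r)
  s <- 0
  for (i in seq_len(n)) {
    vi <- v[i, ] / sqrt(sum(v[i, ]^2))
    ui <- (r[i, ] - cm) / sqrt(sum((r[i, ] - cm)^2))
    s <- s + vi[1] * ui[2] - vi[2] * ui[1]
  }
  abs(s) / n
}

# exhaustive nearest-neighbor subgroup for one frame and focal fish
subgroup_bruteforce <- function(p, focal, n) {
  np <- nrow(p)
  d <- rep(Inf, np)
  for (j in seq_len(np)) d[j] <- sqrt(sum((p[j, ] - p[focal, ])^2))
  ord <- order(d, seq_len(np))
  ord[seq_len(n)]
}

# deterministic small config for simulator tests; dots override defaults
quick_config <- function(...) {
  args <- list(n_fish = 3, n_steps = 200, burn_in = 0, stride = 1, seed = 11)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
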