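# Independent oracles used across the suite. These deliberately use naive
# formulations (double loops, full enumeration) so they stay independent of
# the package's optimized code paths.

# time-averaged MSD by the direct double loop over all (j, j+n) pairs
brute_force_msd <- function(x, y) {
  N <- length(x)
  vapply(seq_len(N - 1L), function(n) {
    acc <- 0
    for (j in 0:(N - n - 1L)) {
      acc <- acc + (x[j + n + 1L] - x[j + 1L])^2 +
        (y[j + n + 1L] - y[j + 1L])^2
    }
    acc / (N - n)
  }, numeric(1))
}

# exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(m+n, m) rank assignments (tie-free samples)
exact_mann_whitney_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2L, function(idx) sum(idx) - m * (m + 1) / 2)
  # two-sided: double the smaller tail (the convention of exact wilcox.test)
  p_lower <- mean(u_all <= u_obs)
  p_upper <- mean(u_all >= u_obs)
  min(1, 2 * min(p_lower, p_upper))
}

# closed-form diffusion estimator for noise-free displacement sequences
closed_form_D <- function(traj) {
  dx <- diff(traj$x); dy <- diff(traj$y)
  sum(dx^2 + dy^2) / (4 * length(dx) * track_dt(traj))
}

# rigid motion of a track: rotation by theta plus translation
rigid_motion <- function(traj, theta, shift = c(0, 0)) {
  x2 <- cos(theta) * traj$x - sin(theta) * traj$y + shift[1L]
  y2 <- sin(theta) * traj$x + cos(theta) * traj$y + shift[2L]
  spt_track(x = x2, y = y2, frame = traj$frame, dt = track_dt(traj),
            track_id = track_id(traj))
}

# small Brownian track set for reuse
make_brownian <- function(n_tracks, n_steps, D = 0.1, dt = 0.1, seed = 1) {
  simulate_brownian(sim_config(n_tracks = n_tracks, n_steps = n_steps,
                               dt = dt, D = D, seed = seed))
}
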