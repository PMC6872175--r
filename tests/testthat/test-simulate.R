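test_that("Brownian steps have variance 2*D*dt and zero-diffusion tracks are static", {
  ts0 <- simulate_brownian(sim_config(n_tracks = 2, n_steps = 20, D = 0,
                                      seed = 1))
  expect_true(all(vapply(ts0$tracks,
                         function(tr) all(tr$x == tr$x[1L]), logical(1))))

  ts <- simulate_brownian(sim_config(n_tracks = 2, n_steps = 50001,
                                     dt = 0.1, D = 0.1, seed = 2))
  v <- var(diff(ts$tracks[[1L]]$x))
  expect_lt(abs(v / 0.02 - 1), 0.02)   # 2*D*dt = 0.02 um^2 within 2%

  # reproducibility: fixed seed => bit-identical output
  a <- simulate_brownian(sim_config(n_tracks = 3, n_steps = 40, seed = 9))
  b <- simulate_brownian(sim_config(n_tracks = 3, n_steps = 40, seed = 9))
  expect_identical(as.data.frame(a), as.data.frame(b))

  expect_error(sim_config(n_steps = 1), "n_steps")
  expect_error(sim_config(dt = 0), "dt")
})

test_that("ensemble MSD of Brownian tracks is linear with slope 4*D", {
  ts <- make_brownian(1000, 60, D = 0.1, dt = 0.1, seed = 3)
  lags <- 1:10
  ens <- rowMeans(vapply(ts$tracks, function(tr) msd_at_lags(tr, lags),
                         numeric(length(lags))))
  expected <- 4 * 0.1 * lags * 0.1
  expect_lt(max(abs(ens / expected - 1)), 0.05)
})

test_that("square-well tracks stay inside the well and approach the L^2/6 plateau", {
  L <- 0.5
  ts <- simulate_confined(sim_config(n_tracks = 20, n_steps = 3000,
                                     dt = 0.1, D = 0.1,
                                     mode = "confined_square", L = L,
                                     seed = 4))
  xs <- unlist(lapply(ts$tracks, function(tr) c(tr$x, tr$y)))
  expect_true(all(xs >= 0 & xs <= L))

  mx <- rowMeans(vapply(ts$tracks, function(tr) compute_msd(tr)$msd_x,
                        numeric(2999)))
  plateau <- mean(mx[500:1500])
  expect_lt(abs(plateau / (L^2 / 6) - 1), 0.10)
  expect_true(max(mx) < L^2 / 2)

  # a very large well reproduces free Brownian step statistics
  big <- simulate_confined(sim_config(n_tracks = 1, n_steps = 2000,
                                      dt = 0.1, D = 0.1,
                                      mode = "confined_square", L = 100,
                                      seed = 5))
  free <- simulate_brownian(sim_config(n_tracks = 1, n_steps = 2000,
                                       dt = 0.1, D = 0.1, seed = 6))
  ks <- stats::ks.test(diff(big$tracks[[1L]]$x), diff(free$tracks[[1L]]$x))
  expect_gt(ks$p.value, 0.01)

  expect_error(sim_config(mode = "confined_square", L = 0), "L > 0")
})

test_that("parabolic-trap tracks have the stationary spread trap_size/4", {
  ts <- simulate_confined(sim_config(n_tracks = 50, n_steps = 2000,
                                     dt = 0.1, D = 0.1,
                                     mode = "confined_parabolic",
                                     trap_size = 0.2, seed = 7))
  xs <- unlist(lapply(ts$tracks, function(tr) tr$x))
  expect_lt(abs(sd(xs) / 0.05 - 1), 0.05)
  # ~95% of positions inside the 200 nm domain (|x| <= 2 sd per dimension)
  r <- unlist(lapply(ts$tracks, function(tr) sqrt(tr$x^2 + tr$y^2)))
  expect_gt(mean(r <= 0.1 * sqrt(2)), 0.9)
})

test_that("directed motion adds exact drift and reduces to Brownian at v = 0", {
  cfg0 <- sim_config(n_tracks = 2, n_steps = 50, D = 0.05,
                     mode = "directed", v = c(0, 0), seed = 8)
  cfgB <- sim_config(n_tracks = 2, n_steps = 50, D = 0.05, seed = 8)
  expect_equal(as.data.frame(simulate_directed(cfg0)),
               as.data.frame(simulate_brownian(cfgB)))

  det <- simulate_directed(sim_config(n_tracks = 1, n_steps = 10, D = 0,
                                      dt = 0.1, mode = "directed",
                                      v = c(0.1, 0), seed = 9))
  expect_equal(diff(det$tracks[[1L]]$x), rep(0.01, 9))
  expect_equal(diff(det$tracks[[1L]]$y), rep(0, 9))

  # ensemble MSD follows the drift-diffusion parabola 4*D*t + (v*t)^2
  ens <- simulate_directed(sim_config(n_tracks = 400, n_steps = 100,
                                      D = 0.05, dt = 0.1,
                                      mode = "directed", v = c(0.2, 0),
                                      seed = 10))
  m50 <- mean(vapply(ens$tracks, function(tr) msd_at_lags(tr, 50L),
                     numeric(1)))
  t50 <- 50 * 0.1
  expect_lt(abs(m50 / (4 * 0.05 * t50 + (0.2 * t50)^2) - 1), 0.10)
})

test_that("switching simulation follows its Markov chain and Gaussian emissions", {
  P <- matrix(c(0.98, 0.02, 0.02, 0.98), 2, byrow = TRUE)
  sw <- simulate_switching(sim_config(n_tracks = 20, n_steps = 501,
                                      mode = "switching", dt = 0.1,
                                      seed = 11),
                           D_states = c(0.01, 0.2), trans_matrix = P)
  gt <- sw$ground_truth
  expect_equal(nrow(gt), 20 * 500)     # one label per displacement

  # empirical dwell length ~ geometric mean 1/(1-0.98) = 50 frames
  dwell <- unlist(lapply(split(gt$true_state, gt$track_id),
                         function(s) rle(s)$lengths))
  expect_lt(abs(mean(dwell) / 50 - 1), 0.20)

  # empirical transition frequencies converge to the transition matrix
  trans_emp <- matrix(0, 2, 2)
  for (s in split(gt$true_state, gt$track_id)) {
    for (t in seq_len(length(s) - 1L))
      trans_emp[s[t], s[t + 1L]] <- trans_emp[s[t], s[t + 1L]] + 1
  }
  trans_emp <- trans_emp / rowSums(trans_emp)
  n_trans <- 20 * 499
  se <- sqrt(0.98 * 0.02 / (n_trans / 2))
  expect_lt(max(abs(diag(trans_emp) - 0.98)), 3 * se)

  # a single state collapses to plain Brownian statistics
  one <- simulate_switching(sim_config(n_tracks = 1, n_steps = 2001,
                                       mode = "switching", dt = 0.1,
                                       seed = 12),
                            D_states = 0.05, trans_matrix = matrix(1, 1, 1))
  v <- var(diff(one$tracks$tracks[[1L]]$x))
  expect_lt(abs(v / (2 * 0.05 * 0.1) - 1), 0.10)

  expect_error(
    simulate_switching(sim_config(n_tracks = 1, n_steps = 10,
                                  mode = "switching"),
                       D_states = c(0.1, 0.2),
                       trans_matrix = matrix(c(0.5, 0.4, 0.5, 0.5), 2)),
    "row-stochastic")
})

test_that("localization noise adds the expected displacement variance", {
  ts <- simulate_brownian(sim_config(n_tracks = 50, n_steps = 200, D = 0,
                                     mode = "immobile", seed = 13))
  same <- add_localization_noise(ts, 0, seed = 1)
  expect_equal(as.data.frame(same), as.data.frame(ts))

  noisy <- add_localization_noise(ts, 0.025, seed = 2)
  # original unmodified
  expect_true(all(ts$tracks[[1L]]$x == ts$tracks[[1L]]$x[1L]))
  d <- unlist(lapply(noisy$tracks, function(tr) diff(tr$x)))
  expect_lt(abs(sd(d) / (sqrt(2) * 0.025) - 1), 0.03)

  # short-lag MSD intercept of noisy Brownian tracks ~ 4*sigma^2
  tsb <- make_brownian(1500, 100, D = 0.1, dt = 0.1, seed = 14)
  tsn <- add_localization_noise(tsb, 0.025, seed = 3)
  offs <- vapply(tsn$tracks, function(tr) fit_d24(tr)$offset, numeric(1))
  expect_lt(abs(mean(offs) / (4 * 0.025^2) - 1), 0.25)

  expect_error(add_localization_noise(ts, -1), "sigma")
})

test_that("blinking removes bounded gap runs and keeps the track ends", {
  ts <- make_brownian(100, 100, seed = 15)
  same <- add_blinking(ts, 0, seed = 1)
  expect_equal(as.data.frame(same), as.data.frame(ts))

  blinked <- add_blinking(ts, 0.1, blink_max_gap = 10, seed = 2)
  n_removed <- 100 * 100 - sum(vapply(blinked$tracks, nrow, integer(1)))
  expect_lt(abs(n_removed / 10000 - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
  for (tr in blinked$tracks) {
    expect_equal(tr$frame[1L], 0L)
    expect_equal(tr$frame[nrow(tr)], 99L)
    expect_true(all(diff(tr$frame) - 1L <= 10L))
  }

  heavy <- add_blinking(make_brownian(50, 200, seed = 16), 0.6,
                        blink_max_gap = 10, seed = 3)
  gaps <- unlist(lapply(heavy$tracks, function(tr) diff(tr$frame) - 1L))
  expect_true(all(gaps <= 10L))

  expect_warning(add_blinking(ts, 0.05, blink_max_gap = 12, seed = 4),
                 "continuity")
})
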