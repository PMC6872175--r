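test_that("RD is 1 for exactly linear MSD and deviates by motion mode", {
  # a deterministic helical-like track is hard to craft with exact MSD, so
  # check the identity through the definition: rd = msd25 / (4 * D24 * 2.5)
  tr <- make_brownian(1, 120, seed = 41)$tracks[[1L]]
  r <- compute_rd(tr)
  expect_equal(r$rd,
               msd_at_lags(tr, 25L) / (4 * r$d24 * 25 * 0.1),
               tolerance = 1e-12)

  # Brownian ensembles centre on 1 (the free-diffusion null)
  ts <- make_brownian(1000, 300, D = 0.1, dt = 0.1, seed = 42)
  rd <- vapply(ts$tracks, function(tr) compute_rd(tr)$rd, numeric(1))
  expect_lt(abs(mean(rd) - 1), 0.05)

  # confinement depresses RD (paper's acquisition regime: 33 Hz, DAT-like D)
  conf <- simulate_confined(sim_config(n_tracks = 150, n_steps = 300,
                                       dt = 1 / 33, D = 0.027,
                                       mode = "confined_square", L = 0.2,
                                       seed = 43))
  rdc <- vapply(conf$tracks, function(tr) compute_rd(tr)$rd, numeric(1))
  expect_lt(mean(rdc, na.rm = TRUE), 0.5)

  # drift inflates RD
  dirs <- simulate_directed(sim_config(n_tracks = 150, n_steps = 300,
                                       dt = 0.1, D = 0.05,
                                       mode = "directed", v = c(0.2, 0),
                                       seed = 44))
  rdd <- vapply(dirs$tracks, function(tr) compute_rd(tr)$rd, numeric(1))
  expect_gt(mean(rdd), 1)

  expect_error(compute_rd(make_brownian(1, 40, seed = 45)$tracks[[1L]]),
               "N >= 2n")
})

test_that("RD is invariant under rigid motion, rescaling with D, and dt", {
  tr <- make_brownian(1, 200, D = 0.05, dt = 0.1, seed = 46)$tracks[[1L]]
  r0 <- compute_rd(tr)$rd
  expect_equal(compute_rd(rigid_motion(tr, 1.1, c(2, 3)))$rd, r0,
               tolerance = 1e-9)

  # uniform spatial rescaling (track and D together): RD unchanged
  sc <- spt_track(x = tr$x * 3, y = tr$y * 3, frame = tr$frame, dt = 0.1)
  expect_equal(compute_rd(sc)$rd, r0, tolerance = 1e-9)

  # same displacements on a different time grid: RD unchanged
  fast <- spt_track(x = tr$x, y = tr$y, frame = tr$frame, dt = 1 / 33)
  expect_equal(compute_rd(fast)$rd, r0, tolerance = 1e-9)
})

test_that("calibration produces ordered percentile bands that narrow with length", {
  calib <- shared_calib
  expect_true(all(calib$p_lower < 1))
  expect_true(all(calib$p_upper > 1))
  width <- calib$p_upper - calib$p_lower
  expect_lt(width[calib$lengths == 600], width[calib$lengths == 100])

  # reproducible bit-exactly under a fixed seed
  again <- calibrate_rd_cutoffs(n_per_length = 300, seed = 4242)
  expect_identical(calib$p_lower, again$p_lower)
  expect_identical(calib$upper_fit, again$upper_fit)

  # boundaries approximately D-independent (RD is dimensionless)
  alt <- calibrate_rd_cutoffs(n_per_length = 300, D = 0.01, seed = 97)
  b1 <- rd_boundaries(calib, c(200, 400))
  b2 <- rd_boundaries(alt, c(200, 400))
  expect_lt(max(abs(b1$lower / b2$lower - 1)), 0.05)

  expect_error(calibrate_rd_cutoffs(lengths = c(100, 200), seed = 1),
               ">= 5 lengths")
  expect_error(calibrate_rd_cutoffs(n_per_length = 50, seed = 1),
               "100 tracks")
})

test_that("calibration round-trips through JSON", {
  f <- tempfile(fileext = ".json")
  save_rd_calibration(shared_calib, f)
  back <- load_rd_calibration(f)
  expect_equal(back$p_lower, shared_calib$p_lower)
  expect_equal(back$lower_fit, shared_calib$lower_fit)
  expect_equal(back$upper_fit, shared_calib$upper_fit)
  expect_equal(rd_boundaries(back, 250), rd_boundaries(shared_calib, 250))
})

test_that("classify_track applies the lower-line rule with extrapolation warnings", {
  calib <- shared_calib
  expect_equal(classify_track(1, calib, N = 300), "free")
  expect_equal(classify_track(0.01, calib, N = 300), "restricted")
  # above the upper band still free: directed transport is ignored
  expect_equal(classify_track(3, calib, N = 300), "free")
  expect_warning(classify_track(1, calib, N = 1000), "extrapolated")
  expect_true(is.na(classify_track(NA_real_, calib, N = 300)))
})

test_that("classifier power and specificity on labelled ensembles", {
  calib <- shared_calib
  conf <- simulate_confined(sim_config(n_tracks = 100, n_steps = 300,
                                       dt = 1 / 33, D = 0.027,
                                       mode = "confined_square", L = 0.2,
                                       seed = 48))
  labs <- vapply(conf$tracks, function(tr) {
    r <- compute_rd(tr)
    if (r$unclassifiable) NA_character_
    else suppressWarnings(classify_track(r, calib))
  }, character(1))
  expect_gt(mean(labs == "restricted", na.rm = TRUE), 0.8)

  free <- make_brownian(200, 300, D = 0.1, dt = 0.1, seed = 49)
  labf <- vapply(free$tracks, function(tr)
    suppressWarnings(classify_track(compute_rd(tr), calib)), character(1))
  expect_gt(mean(labf == "free"), 0.9)

  # specificity against the raw calibrated percentile is 2.5% by design
  rd_fresh <- vapply(make_brownian(1000, 300, D = 0.1, seed = 50)$tracks,
                     function(tr) compute_rd(tr)$rd, numeric(1))
  p25 <- shared_calib$p_lower[shared_calib$lengths == 300]
  expect_lt(abs(mean(rd_fresh < p25) - 0.025), 0.015)
})

test_that("classify_trackset separates immobile, restricted and free pools", {
  imm <- add_localization_noise(
    simulate_brownian(sim_config(n_tracks = 20, n_steps = 100, D = 0,
                                 mode = "immobile", seed = 51)),
    0.025, seed = 52)
  imm$tracks <- lapply(seq_along(imm$tracks), function(i) {
    tr <- imm$tracks[[i]]
    attr(tr, "track_id") <- paste0("imm", i); tr
  })
  onlyimm <- spt_trackset(imm$tracks)
  res <- classify_trackset(onlyimm, shared_calib)
  expect_equal(unname(res$fractions["immobile"]), 1)

  mix <- c(
    make_brownian(30, 300, D = 0.05, dt = 1 / 33, seed = 53)$tracks,
    simulate_confined(sim_config(n_tracks = 30, n_steps = 300, dt = 1 / 33,
                                 D = 0.027, mode = "confined_square",
                                 L = 0.2, seed = 54))$tracks)
  mix <- lapply(seq_along(mix), function(i) {
    tr <- mix[[i]]; attr(tr, "track_id") <- paste0("m", i); tr
  })
  res2 <- classify_trackset(spt_trackset(mix), shared_calib)
  expect_equal(nrow(res2$per_track), 60L)
  expect_gt(res2$fractions["restricted"], 0.4)
  expect_lt(res2$fractions["restricted"], 0.6)
  expect_equal(sum(res2$fractions), 1)
})
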