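#' Simulation configuration
#'
#' Collects the parameters of a synthetic-trajectory scenario. Positions
#' are in micrometres and times in seconds throughout.
#'
#' @param n_tracks Number of trajectories.
#' @param n_steps Number of frames (positions) per trajectory, >= 2.
#' @param dt Frame interval in seconds.
#' @param D Diffusion coefficient in um^2/s.
#' @param mode One of `"brownian"`, `"confined_square"`,
#'   `"confined_parabolic"`, `"directed"`, `"immobile"`, `"switching"`.
#' @param L Side of the reflective square well in um (`confined_square`).
#' @param trap_size Confinement-domain diameter in um
#'   (`confined_parabolic`); the mean-reverting update is parameterized so
#'   that the stationary standard deviation per dimension is `trap_size/4`,
#'   placing ~95% of positions inside the domain.
#' @param v Drift velocity vector `c(vx, vy)` in um/s (`directed`).
#' @param loc_sigma Localization-noise standard deviation in um (applied
#'   separately via [add_localization_noise()]; recorded here as metadata).
#' @param blink_p Per-frame blinking (off) probability.
#' @param blink_max_gap Longest blink run in frames (<= 10).
#' @param seed Integer seed; every stochastic operation is reproducible
#'   under a fixed seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_tracks = 1L, n_steps = 100L, dt = 0.1, D = 0.1,
                       mode = c("brownian", "confined_square",
                                "confined_parabolic", "directed",
                                "immobile", "switching"),
                       L = NULL, trap_size = NULL, v = c(0, 0),
                       loc_sigma = 0, blink_p = 0, blink_max_gap = 10L,
                       seed = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(n_steps) || n_steps < 2L)
    stop("invalid config: n_steps must be >= 2", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0)
    stop("invalid config: dt must be positive", call. = FALSE)
  if (!is.numeric(D) || D < 0)
    stop("invalid config: D must be >= 0", call. = FALSE)
  if (mode == "confined_square" && (is.null(L) || L <= 0))
    stop("invalid config: confined_square needs L > 0", call. = FALSE)
  if (mode == "confined_parabolic" && (is.null(trap_size) || trap_size <= 0))
    stop("invalid config: confined_parabolic needs trap_size > 0",
         call. = FALSE)
  if (!is.numeric(v) || length(v) != 2L)
    stop("invalid config: v must be a length-2 numeric vector", call. = FALSE)
  if (loc_sigma < 0)
    stop("invalid config: loc_sigma must be >= 0", call. = FALSE)
  if (blink_p < 0 || blink_p >= 1)
    stop("invalid config: blink_p must be in [0, 1)", call. = FALSE)
  if (blink_max_gap > 10L)
    warning("blink_max_gap > 10 exceeds the usual continuity window",
            call. = FALSE)
  structure(list(n_tracks = as.integer(n_tracks),
                 n_steps = as.integer(n_steps), dt = dt, D = D, mode = mode,
                 L = L, trap_size = trap_size, v = v, loc_sigma = loc_sigma,
                 blink_p = blink_p, blink_max_gap = as.integer(blink_max_gap),
                 seed = seed),
            class = "sim_config")
}

.set_seed <- function(seed) if (!is.null(seed)) set.seed(as.integer(seed))

.matrix_to_trackset <- function(X, Y, cfg, prefix = "sim") {
  tracks <- lapply(seq_len(ncol(X)), function(i)
    spt_track(x = X[, i], y = Y[, i], dt = cfg$dt,
              track_id = paste0(prefix, i)))
  ts <- spt_trackset(tracks, dt = cfg$dt, loc_sigma = cfg$loc_sigma,
                     source = paste0("simulated:", cfg$mode))
  attr(ts, "true_mode") <- cfg$mode
  attr(ts, "true_D") <- cfg$D
  ts
}

#' Simulate 2D Brownian trajectories
#'
#' Each per-dimension step is drawn from a Gaussian with variance
#' `2 * D * dt`, so the ensemble MSD is `4 * D * t`.
#'
#' @param cfg A [sim_config()] with `mode = "brownian"` (or `"immobile"`,
#'   which is the `D = 0` case).
#' @return An [spt_trackset()] carrying `true_mode`/`true_D` attributes.
#' @export
simulate_brownian <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$mode %in% c("brownian", "immobile"))
    stop("invalid config: mode must be brownian or immobile", call. = FALSE)
  D <- if (cfg$mode == "immobile") 0 else cfg$D
  .set_seed(cfg$seed)
  s <- sqrt(2 * D * cfg$dt)
  n <- cfg$n_steps; m <- cfg$n_tracks
  step_x <- matrix(stats::rnorm((n - 1L) * m, sd = s), n - 1L, m)
  step_y <- matrix(stats::rnorm((n - 1L) * m, sd = s), n - 1L, m)
  X <- rbind(0, apply(step_x, 2L, cumsum))
  Y <- rbind(0, apply(step_y, 2L, cumsum))
  if (s == 0) { X <- matrix(0, n, m); Y <- matrix(0, n, m) }
  .matrix_to_trackset(X, Y, cfg)
}

# triangular fold of unbounded coordinates into [0, L] (method of images)
.fold_reflect <- function(z, L) {
  z <- z %% (2 * L)
  ifelse(z > L, 2 * L - z, z)
}

#' Simulate confined trajectories
#'
#' Two confinement models are provided. `confined_square` performs Brownian
#' steps with reflective boundaries on the square `[0, L]^2` (free Brownian
#' diffusion inside an infinitely high square-well potential); its
#' per-dimension MSD asymptotically approaches `L^2/6`. `confined_parabolic`
#' uses an exact mean-reverting (Ornstein-Uhlenbeck) update around the
#' domain centre whose stationary standard deviation is `trap_size/4` per
#' dimension and whose short-time step variance matches `2 * D * dt`.
#'
#' @param cfg A [sim_config()] with a confined mode.
#' @return An [spt_trackset()].
#' @export
simulate_confined <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$mode %in% c("confined_square", "confined_parabolic"))
    stop("invalid config: mode must be a confined mode", call. = FALSE)
  .set_seed(cfg$seed)
  n <- cfg$n_steps; m <- cfg$n_tracks
  X <- matrix(0, n, m); Y <- matrix(0, n, m)
  if (cfg$mode == "confined_square") {
    L <- cfg$L
    s <- sqrt(2 * cfg$D * cfg$dt)
    X[1L, ] <- stats::runif(m, 0, L)
    Y[1L, ] <- stats::runif(m, 0, L)
    for (k in 2:n) {
      X[k, ] <- .fold_reflect(X[k - 1L, ] + stats::rnorm(m, sd = s), L)
      Y[k, ] <- .fold_reflect(Y[k - 1L, ] + stats::rnorm(m, sd = s), L)
    }
  } else {
    sd_stat <- cfg$trap_size / 4
    theta <- cfg$D / sd_stat^2        # so that stationary var = D/theta
    phi <- exp(-theta * cfg$dt)
    s_xi <- sd_stat * sqrt(1 - phi^2) # exact OU discretization
    X[1L, ] <- stats::rnorm(m, sd = sd_stat)
    Y[1L, ] <- stats::rnorm(m, sd = sd_stat)
    for (k in 2:n) {
      X[k, ] <- phi * X[k - 1L, ] + stats::rnorm(m, sd = s_xi)
      Y[k, ] <- phi * Y[k - 1L, ] + stats::rnorm(m, sd = s_xi)
    }
  }
  .matrix_to_trackset(X, Y, cfg)
}

#' Simulate directed (drift + diffusion) trajectories
#'
#' Positions are a Brownian walk with variance `2 * D * dt` per dimension
#' plus a deterministic drift `v * t`; the ensemble MSD is the parabola
#' `4*D*t + (|v| t)^2`.
#'
#' @param cfg A [sim_config()] with `mode = "directed"`.
#' @return An [spt_trackset()].
#' @export
simulate_directed <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mode != "directed")
    stop("invalid config: mode must be directed", call. = FALSE)
  base <- cfg; base$mode <- "brownian"
  class(base) <- "sim_config"
  ts <- simulate_brownian(base)
  tt <- (seq_len(cfg$n_steps) - 1L) * cfg$dt
  ts$tracks <- lapply(ts$tracks, function(tr) {
    tr$x <- tr$x + cfg$v[1L] * tt
    tr$y <- tr$y + cfg$v[2L] * tt
    tr
  })
  names(ts$tracks) <- vapply(ts$tracks, track_id, character(1))
  attr(ts, "true_mode") <- "directed"
  attr(ts, "true_D") <- cfg$D
  ts
}

#' Simulate trajectories that switch between diffusive states
#'
#' A hidden state evolves as a first-order Markov chain with transition
#' matrix `trans_matrix`; while in state `k` each per-dimension displacement
#' is drawn from a zero-mean Gaussian with variance `2 * D_states[k] * dt`.
#' The ground-truth state sequence (one label per displacement, i.e. per
#' frame transition) is returned alongside the tracks.
#'
#' @param cfg A [sim_config()] with `mode = "switching"`.
#' @param D_states Numeric vector of per-state diffusion coefficients
#'   (um^2/s), all >= 0.
#' @param trans_matrix Row-stochastic K x K transition matrix.
#' @param init Initial state distribution (default: stationary distribution
#'   of `trans_matrix`).
#' @return A list with elements `tracks` (an [spt_trackset()]) and
#'   `ground_truth` (data frame `track_id, step, true_state, true_D`; `step`
#'   indexes displacements, 1-based).
#' @export
simulate_switching <- function(cfg, D_states, trans_matrix, init = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mode != "switching")
    stop("invalid config: mode must be switching", call. = FALSE)
  D_states <- as.numeric(D_states)
  if (any(D_states < 0))
    stop("invalid config: D_states must be >= 0", call. = FALSE)
  K <- length(D_states)
  trans_matrix <- as.matrix(trans_matrix)
  if (nrow(trans_matrix) != K || ncol(trans_matrix) != K ||
      any(trans_matrix < 0) ||
      any(abs(rowSums(trans_matrix) - 1) > 1e-8))
    stop("invalid config: trans_matrix must be a row-stochastic KxK matrix",
         call. = FALSE)
  if (is.null(init)) init <- stationary_distribution(trans_matrix)
  .set_seed(cfg$seed)
  n <- cfg$n_steps; m <- cfg$n_tracks
  n_disp <- n - 1L
  # state chain, vectorized across tracks
  S <- matrix(0L, n_disp, m)
  S[1L, ] <- .sample_states(matrix(init, m, K, byrow = TRUE))
  if (n_disp > 1L) for (k in 2:n_disp)
    S[k, ] <- .sample_states(trans_matrix[S[k - 1L, ], , drop = FALSE])
  sd_state <- sqrt(2 * D_states * cfg$dt)
  step_x <- matrix(stats::rnorm(n_disp * m), n_disp, m) * sd_state[S]
  step_y <- matrix(stats::rnorm(n_disp * m), n_disp, m) * sd_state[S]
  X <- rbind(0, apply(step_x, 2L, cumsum))
  Y <- rbind(0, apply(step_y, 2L, cumsum))
  ts <- .matrix_to_trackset(X, Y, cfg)
  attr(ts, "true_D") <- D_states
  gt <- data.frame(
    track_id = rep(vapply(ts$tracks, track_id, character(1)),
                   each = n_disp),
    step = rep(seq_len(n_disp), times = m),
    true_state = as.integer(S),
    true_D = D_states[as.integer(S)])
  list(tracks = ts, ground_truth = gt)
}

# one categorical draw per row of a row-stochastic probability matrix
.sample_states <- function(P) {
  u <- stats::runif(nrow(P))
  cum <- t(apply(P, 1L, cumsum))
  as.integer(rowSums(u > cum) + 1L)
}

#' Stationary distribution of a Markov transition matrix
#'
#' @param P Row-stochastic square matrix.
#' @return Probability vector `p` with `p %*% P = p`.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  p <- Re(e$vectors[, i])
  p / sum(p)
}

#' Add Gaussian localization noise to trajectories
#'
#' Independent zero-mean Gaussian noise of standard deviation `loc_sigma`
#' is added to every coordinate, emulating the static localization error of
#' the detector (~25 nm for bright quantum dots). Optionally the per-track
#' sigma is drawn from a truncated Gaussian (`sigma_sd > 0`) to mirror a
#' 25 +/- 10 nm spread across emitters. The input object is not modified.
#'
#' @param ts An [spt_trackset()].
#' @param loc_sigma Noise standard deviation in um (mean value when
#'   `sigma_sd > 0`).
#' @param sigma_sd Across-track spread of sigma in um; per-track values are
#'   truncated below at `sigma_floor`.
#' @param sigma_floor Smallest admissible per-track sigma in um.
#' @param seed Optional integer seed.
#' @return A new [spt_trackset()] with noisy coordinates.
#' @export
add_localization_noise <- function(ts, loc_sigma = 0.025, sigma_sd = 0,
                                   sigma_floor = 0.005, seed = NULL) {
  stopifnot(inherits(ts, "spt_trackset"))
  if (loc_sigma < 0 || sigma_sd < 0)
    stop("invalid config: negative sigma", call. = FALSE)
  .set_seed(seed)
  sig <- rep(loc_sigma, length(ts$tracks))
  if (sigma_sd > 0)
    sig <- pmax(stats::rnorm(length(ts$tracks), loc_sigma, sigma_sd),
                sigma_floor)
  out <- ts
  out$tracks <- lapply(seq_along(ts$tracks), function(i) {
    tr <- ts$tracks[[i]]
    tr$x <- tr$x + stats::rnorm(nrow(tr), sd = sig[i])
    tr$y <- tr$y + stats::rnorm(nrow(tr), sd = sig[i])
    tr
  })
  names(out$tracks) <- names(ts$tracks)
  out$loc_sigma <- loc_sigma
  out
}

#' Remove frames to emulate fluorophore blinking
#'
#' Each interior frame is switched off with probability `blink_p`, except
#' that off-runs are capped at `blink_max_gap` frames (an emitter dark for
#' longer would not be re-linked into the same track) and the first and
#' last frames are always retained. Frame indices of surviving points are
#' unchanged, so the resulting tracks carry real gaps that
#' [reindex_blink_gaps()] can later close.
#'
#' @param ts An [spt_trackset()].
#' @param blink_p Per-frame off probability in `[0, 1)`.
#' @param blink_max_gap Longest allowed off-run in frames; values > 10
#'   trigger a warning (they exceed the usual linking window).
#' @param seed Optional integer seed.
#' @return A new [spt_trackset()] with missing frames.
#' @export
add_blinking <- function(ts, blink_p, blink_max_gap = 10L, seed = NULL) {
  stopifnot(inherits(ts, "spt_trackset"))
  if (blink_p < 0 || blink_p >= 1)
    stop("invalid config: blink_p must be in [0, 1)", call. = FALSE)
  if (blink_max_gap > 10L)
    warning("blink_max_gap > 10 exceeds the usual continuity window",
            call. = FALSE)
  .set_seed(seed)
  out <- ts
  out$tracks <- lapply(ts$tracks, function(tr) {
    n <- nrow(tr)
    off <- stats::runif(n) < blink_p
    off[c(1L, n)] <- FALSE
    run <- 0L
    for (k in seq_len(n)) {      # cap off-runs at blink_max_gap
      if (off[k]) {
        run <- run + 1L
        if (run > blink_max_gap) { off[k] <- FALSE; run <- 0L }
      } else run <- 0L
    }
    keep <- which(!off)
    spt_track(x = tr$x[keep], y = tr$y[keep], frame = tr$frame[keep],
              dt = track_dt(tr), track_id = track_id(tr))
  })
  names(out$tracks) <- names(ts$tracks)
  out
}

#' Simulate a trajectory scenario
#'
#' Convenience dispatcher over the mode-specific simulators, optionally
#' applying localization noise and blinking in one call.
#'
#' @param cfg A [sim_config()].
#' @param D_states,trans_matrix Passed to [simulate_switching()] when
#'   `mode = "switching"`.
#' @return An [spt_trackset()]; for `mode = "switching"` a list as returned
#'   by [simulate_switching()].
#' @export
simulate_tracks <- function(cfg, D_states = NULL, trans_matrix = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  out <- switch(cfg$mode,
    brownian = ,
    immobile = simulate_brownian(cfg),
    confined_square = ,
    confined_parabolic = simulate_confined(cfg),
    directed = simulate_directed(cfg),
    switching = simulate_switching(cfg, D_states, trans_matrix))
  post <- function(ts) {
    if (cfg$loc_sigma > 0) ts <- add_localization_noise(ts, cfg$loc_sigma)
    if (cfg$blink_p > 0) ts <- add_blinking(ts, cfg$blink_p, cfg$blink_max_gap)
    ts
  }
  if (cfg$mode == "switching") { out$tracks <- post(out$tracks); out }
  else post(out)
}

#' Write a switching-simulation ground truth to CSV
#'
#' @param gt Ground-truth data frame from [simulate_switching()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  utils::write.csv(gt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
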