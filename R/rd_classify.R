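#' Relative-deviation statistic of a trajectory
#'
#' The relative deviation at lag `n` compares the observed time-averaged
#' MSD with the value expected under free Brownian motion extrapolated
#' from the initial slope:
#' `RD(N, n) = MSD(n*dt) / (4 * D_24 * n * dt)`,
#' with `D_24` from the first-four-lag linear fit ([fit_d24()]; the fitted
#' offset is not part of the denominator). For simple diffusion RD averages
#' 1; confinement caps the numerator (RD < 1) and drift inflates it
#' (RD > 1).
#'
#' @param traj A reindexed [spt_track()] with `N >= 2*n` points.
#' @param n Lag index in frames (default 25).
#' @param d24 Optionally a precomputed `D_24`; computed from the track when
#'   missing.
#' @return List with `rd` (NA when `D_24 <= 0`, with `unclassifiable`
#'   TRUE), `n`, `N` and `d24`.
#' @export
compute_rd <- function(traj, n = 25L, d24 = NULL) {
  stopifnot(inherits(traj, "spt_track"))
  N <- nrow(traj)
  if (N < 2L * n)
    stop("RD(N, n) needs N >= 2n points for a well-averaged lag-n MSD",
         call. = FALSE)
  if (is.null(d24)) d24 <- fit_d24(traj)$D_24
  dt <- track_dt(traj)
  if (!is.finite(d24) || d24 <= 0)
    return(list(rd = NA_real_, n = as.integer(n), N = N, d24 = d24,
                unclassifiable = TRUE))
  msd_n <- msd_at_lags(traj, n)
  list(rd = msd_n / (4 * d24 * n * dt), n = as.integer(n), N = N,
       d24 = d24, unclassifiable = FALSE)
}

#' Calibrate relative-deviation percentile boundaries by simulation
#'
#' Simulates noise-free Brownian trajectories at each requested track
#' length, computes `RD(N, n)` for every track, and records the empirical
#' 2.5th and 97.5th percentiles per length. RD values inside that band
#' represent statistical variation of Brownian motion. The lower boundary
#' used for classification is a linear least-squares fit of the 2.5th
#' percentile points against `N`; the upper boundary is a 4th-order
#' polynomial fit of the 97.5th percentile points (requires >= 5 lengths).
#'
#' Because RD is dimensionless the boundaries are essentially independent
#' of the calibration `D` and `dt`; the defaults follow the standard
#' construction (D = 0.1 um^2/s, lengths 100-600, 1000 tracks per length).
#'
#' @param lengths Track lengths (frames) to calibrate at.
#' @param n_per_length Simulated tracks per length (>= 100).
#' @param D Calibration diffusion coefficient (um^2/s).
#' @param dt Frame interval (s).
#' @param n_lag RD lag in frames (default 25).
#' @param probs Lower/upper percentile pair (default 2.5% / 97.5%).
#' @param seed Integer seed; the calibration is bit-reproducible under a
#'   fixed seed.
#' @return An object of class `rd_calibration`: lengths, per-length
#'   percentiles `p_lower`/`p_upper`, `lower_fit` (intercept, slope),
#'   `upper_fit` (5 polynomial coefficients, ascending powers), and the
#'   simulation parameters.
#' @export
calibrate_rd_cutoffs <- function(lengths = c(100L, 200L, 300L, 400L, 500L,
                                             600L),
                                 n_per_length = 1000L, D = 0.1, dt = 0.1,
                                 n_lag = 25L, probs = c(0.025, 0.975),
                                 seed = NULL) {
  lengths <- sort(unique(as.integer(lengths)))
  if (length(lengths) < 2L)
    stop("calibration needs at least 2 distinct lengths", call. = FALSE)
  if (n_per_length < 100L)
    stop("calibration needs at least 100 tracks per length", call. = FALSE)
  if (length(lengths) < 5L)
    stop("a 4th-order upper boundary fit needs >= 5 lengths", call. = FALSE)
  .set_seed(seed)
  p_lower <- p_upper <- numeric(length(lengths))
  for (i in seq_along(lengths)) {
    cfg <- sim_config(n_tracks = n_per_length, n_steps = lengths[i],
                      dt = dt, D = D, mode = "brownian")
    ts <- simulate_brownian(cfg)
    rd <- vapply(ts$tracks, function(tr) compute_rd(tr, n = n_lag)$rd,
                 numeric(1))
    rd <- rd[is.finite(rd)]
    q <- stats::quantile(rd, probs, names = FALSE, type = 7)
    p_lower[i] <- q[1L]; p_upper[i] <- q[2L]
  }
  lower_fit <- stats::lm.fit(cbind(1, lengths), p_lower)$coefficients
  upper_fit <- stats::lm.fit(outer(lengths, 0:4, `^`), p_upper)$coefficients
  structure(list(lengths = lengths, p_lower = p_lower, p_upper = p_upper,
                 lower_fit = unname(lower_fit),
                 upper_fit = unname(upper_fit),
                 n_lag = as.integer(n_lag), probs = probs,
                 sim_params = list(n_per_length = as.integer(n_per_length),
                                   D = D, dt = dt, seed = seed)),
            class = "rd_calibration")
}

#' Evaluate the fitted RD boundaries at a track length
#'
#' @param calib An `rd_calibration`.
#' @param N Track length(s) in frames.
#' @return Data frame with `N`, `lower` (line) and `upper` (4th-order
#'   polynomial).
#' @export
rd_boundaries <- function(calib, N) {
  stopifnot(inherits(calib, "rd_calibration"))
  lower <- calib$lower_fit[1L] + calib$lower_fit[2L] * N
  pw <- outer(N, 0:4, `^`)
  upper <- drop(pw %*% calib$upper_fit)
  data.frame(N = N, lower = lower, upper = upper)
}

#' Classify one track's motion from its relative deviation
#'
#' Tracks below the fitted lower RD boundary at their length are
#' `restricted`; everything else is `free`. Values above the upper
#' boundary would indicate directed transport, which membrane proteins are
#' not subject to here, so they are folded into `free`. Lengths outside
#' the calibrated range (+/- 50 frames) trigger an extrapolation warning.
#'
#' @param rd An RD result from [compute_rd()] (or a bare numeric RD value,
#'   in which case `N` must be given).
#' @param calib An `rd_calibration`.
#' @param N Track length in frames (taken from `rd` when it is a
#'   [compute_rd()] result).
#' @return `"restricted"`, `"free"`, or `NA` for unclassifiable input.
#' @export
classify_track <- function(rd, calib, N = NULL) {
  stopifnot(inherits(calib, "rd_calibration"))
  if (is.list(rd)) { N <- rd$N; rd <- rd$rd }
  if (is.null(N)) stop("track length N required", call. = FALSE)
  if (!is.finite(rd)) return(NA_character_)
  rng <- range(calib$lengths)
  if (N < rng[1L] - 50L || N > rng[2L] + 50L)
    warning("track length ", N, " outside the calibrated range ",
            rng[1L], "-", rng[2L], "; boundary extrapolated", call. = FALSE)
  lower <- calib$lower_fit[1L] + calib$lower_fit[2L] * N
  if (rd < lower) "restricted" else "free"
}

#' Classify a whole track set
#'
#' Runs the full per-track decision: tracks with `D_mle` below the
#' immobility cutoff are `immobile` and excluded from RD analysis; among
#' the mobile tracks those with non-positive `D_24` are `unclassifiable`;
#' the rest are `restricted` or `free` by [classify_track()].
#'
#' @param ts An [spt_trackset()] of reindexed tracks (each >= `2*n_lag`
#'   points).
#' @param calib An `rd_calibration`.
#' @param loc_sigma,blur_R Passed to [estimate_d_mle()].
#' @param immobile_threshold Cutoff for [classify_immobile()] (um^2/s).
#' @param n_lag RD lag (frames).
#' @return List with `per_track` (data frame: track_id, N, D_mle, D_24,
#'   rd, label) and `fractions` (named fractions per label).
#' @export
classify_trackset <- function(ts, calib, loc_sigma = 0.025, blur_R = 1/6,
                              immobile_threshold = 5e-4, n_lag = 25L) {
  stopifnot(inherits(ts, "spt_trackset"), inherits(calib, "rd_calibration"))
  rows <- lapply(ts$tracks, function(tr) {
    d_mle <- estimate_d_mle(tr, loc_sigma = loc_sigma, blur_R = blur_R)$D_mle
    if (classify_immobile(d_mle, immobile_threshold))
      return(data.frame(track_id = track_id(tr), N = nrow(tr),
                        D_mle = d_mle, D_24 = NA_real_, rd = NA_real_,
                        label = "immobile"))
    rd <- compute_rd(tr, n = n_lag)
    label <- if (rd$unclassifiable) "unclassifiable"
             else suppressWarnings(classify_track(rd, calib))
    data.frame(track_id = track_id(tr), N = nrow(tr), D_mle = d_mle,
               D_24 = rd$d24, rd = rd$rd, label = label)
  })
  per_track <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  tab <- table(factor(per_track$label,
                      levels = c("immobile", "restricted", "free",
                                 "unclassifiable")))
  fractions <- as.numeric(tab) / nrow(per_track)
  names(fractions) <- names(tab)
  list(per_track = per_track, fractions = fractions)
}

#' Save / load an RD calibration as JSON
#'
#' Persists the calibrated lengths, raw percentiles, fitted boundary
#' coefficients and simulation parameters for audit and reuse.
#'
#' @param calib An `rd_calibration`.
#' @param path Output path.
#' @return `path` invisibly, or the restored `rd_calibration`.
#' @export
save_rd_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "rd_calibration"))
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_rd_calibration
#' @export
load_rd_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$lengths <- as.integer(obj$lengths)
  obj$n_lag <- as.integer(obj$n_lag)
  structure(obj, class = "rd_calibration")
}
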