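#' Time-averaged mean square displacement of a trajectory
#'
#' For a reindexed track of `N` positions sampled every `dt` seconds, the
#' MSD at lag `n` is the average of the squared displacement over all `N-n`
#' overlapping position pairs `(j, j+n)`:
#' `MSD(n*dt) = mean over j of [x(j+n)-x(j)]^2 + [y(j+n)-y(j)]^2`.
#'
#' The full curve over lags `1..N-1` is evaluated with the exact
#' FFT/cumulative-sum decomposition of the pair sums (O(N log N)), which
#' agrees with the direct double loop to floating-point precision.
#'
#' By default the trajectory must be contiguous (blink gaps closed by
#' [reindex_blink_gaps()], which collapses time across gaps). With
#' `gap_aware = TRUE` the average instead uses the original frame indices
#' (the `"orig_frames"` attribute left by reindexing, or the raw frames of
#' an unreindexed track): lags are true frame differences and pairs
#' spanning missing frames are simply absent from the average, which
#' avoids the time-base bias of collapse for heavily blinking tracks at
#' the price of uneven pair counts.
#'
#' @param traj A reindexed [spt_track()] (contiguous frames), or any
#'   [spt_track()] when `gap_aware = TRUE`.
#' @param gap_aware Average over true frame lags, excluding missing pairs.
#' @return An object of class `msd_curve`: list with `lags` (seconds),
#'   `msd` (um^2, x+y), `msd_x`, `msd_y` (per-dimension components),
#'   `n_pairs` (averaging count per lag), `N` and `dt`.
#' @export
compute_msd <- function(traj, gap_aware = FALSE) {
  stopifnot(inherits(traj, "spt_track"))
  N <- nrow(traj)
  if (N < 2L) stop("MSD needs at least 2 points", call. = FALSE)
  if (gap_aware) return(.msd_gap_aware(traj))
  if (any(diff(traj$frame) != 1L))
    stop("trajectory has frame gaps: reindex_blink_gaps() first",
         call. = FALSE)
  dt <- track_dt(traj)
  mx <- .msd_1d(traj$x)
  my <- .msd_1d(traj$y)
  structure(list(lags = seq_len(N - 1L) * dt, msd = mx + my,
                 msd_x = mx, msd_y = my,
                 n_pairs = N - seq_len(N - 1L), N = N, dt = dt),
            class = "msd_curve")
}

# MSD over true frame lags; pairs across missing frames are excluded
.msd_gap_aware <- function(traj) {
  fr <- attr(traj, "orig_frames")
  if (is.null(fr)) fr <- traj$frame
  dt <- track_dt(traj)
  span <- fr[length(fr)] - fr[1L]
  mx <- my <- np <- numeric(span)
  for (n in seq_len(span)) {
    j <- match(fr + n, fr)
    ok <- which(!is.na(j))
    np[n] <- length(ok)
    if (!length(ok)) next
    mx[n] <- mean((traj$x[j[ok]] - traj$x[ok])^2)
    my[n] <- mean((traj$y[j[ok]] - traj$y[ok])^2)
  }
  keep <- np > 0
  structure(list(lags = which(keep) * dt, msd = (mx + my)[keep],
                 msd_x = mx[keep], msd_y = my[keep], n_pairs = np[keep],
                 N = nrow(traj), dt = dt),
            class = "msd_curve")
}

# per-dimension time-averaged MSD over all lags. Direct pair averaging for
# short tracks (exact to double rounding); the FFT/cumulative-sum
# decomposition MSD(n) = [S1(n) - 2*AC(n)]/(N-n) for long ones, where
#   S1(n) = sum_{j=0}^{N-n-1} ( r_j^2 + r_{j+n}^2 )  (cumulative sums)
#   AC(n) = sum_{j} r_j r_{j+n}                      (FFT)
.msd_1d <- function(r) {
  N <- length(r)
  if (N <= 2048L) {
    return(vapply(seq_len(N - 1L), function(n) {
      d <- r[(1L + n):N] - r[seq_len(N - n)]
      mean(d * d)
    }, numeric(1)))
  }
  .msd_1d_fft(r)
}

.msd_1d_fft <- function(r) {
  N <- length(r)
  nfft <- 2^ceiling(log2(2L * N))
  fr <- stats::fft(c(r, numeric(nfft - N)))
  ac <- Re(stats::fft(fr * Conj(fr), inverse = TRUE))[1:N] / nfft
  sq <- r * r
  cs <- cumsum(sq)          # cs[k] = sum of first k squares
  tot <- cs[N]
  n <- seq_len(N - 1L)
  s1 <- cs[N - n] + (tot - cs[n])
  (s1 - 2 * ac[n + 1L]) / (N - n)
}

#' Time-averaged MSD at selected lags (direct evaluation)
#'
#' Evaluates the same pair-averaged MSD as [compute_msd()] but only at the
#' requested lags, in O(N) per lag; used where only a handful of lags are
#' needed (short-lag fits, the relative-deviation statistic).
#'
#' @param traj A reindexed [spt_track()].
#' @param lags Integer lag indices (frames), all in `1..N-1`.
#' @return Numeric vector of MSD values (um^2).
#' @export
msd_at_lags <- function(traj, lags) {
  stopifnot(inherits(traj, "spt_track"))
  N <- nrow(traj)
  lags <- as.integer(lags)
  if (any(lags < 1L | lags > N - 1L))
    stop("lags must lie in 1..N-1", call. = FALSE)
  if (any(diff(traj$frame) != 1L))
    stop("trajectory has frame gaps: reindex_blink_gaps() first",
         call. = FALSE)
  x <- traj$x; y <- traj$y
  vapply(lags, function(n) {
    i <- seq_len(N - n)
    mean((x[i + n] - x[i])^2 + (y[i + n] - y[i])^2)
  }, numeric(1))
}

#' Short-lag diffusion coefficient D_2-4
#'
#' Ordinary least squares of the first four MSD points against lag time,
#' `MSD(t) = 4 * D_24 * t + offset`, with a free intercept. The intercept
#' absorbs the static localization-noise contribution (~`4*sigma^2`), so
#' `D_24` estimates the microscopic diffusion coefficient independently of
#' the motion mode.
#'
#' @param msd An `msd_curve` from [compute_msd()], or an [spt_track()]
#'   (in which case the needed lags are computed directly).
#' @param n_points Number of leading lags used (default 4).
#' @return List with `D_24` (um^2/s) and `offset` (um^2).
#' @export
fit_d24 <- function(msd, n_points = 4L) {
  if (inherits(msd, "spt_track")) {
    if (nrow(msd) < n_points + 1L)
      stop("track too short for the short-lag fit", call. = FALSE)
    tv <- seq_len(n_points) * track_dt(msd)
    yv <- msd_at_lags(msd, seq_len(n_points))
  } else {
    stopifnot(inherits(msd, "msd_curve"))
    if (length(msd$msd) < n_points)
      stop("MSD curve has fewer than ", n_points, " lags", call. = FALSE)
    tv <- msd$lags[seq_len(n_points)]
    yv <- msd$msd[seq_len(n_points)]
  }
  fit <- stats::lm.fit(cbind(1, tv), yv)
  list(D_24 = unname(fit$coefficients[2L]) / 4,
       offset = unname(fit$coefficients[1L]))
}

#' Anomalous-diffusion exponent fit
#'
#' Fits the whole individual MSD curve to the power law
#' `MSD(t) = 4 * D_alpha * t^alpha` by bounded nonlinear least squares in
#' the linear domain (`alpha` in `[0, 2]`, `D_alpha > 0`), initialized at
#' `alpha = 1` with `D_alpha` from the short-lag fit. `alpha ~ 1` indicates
#' Brownian motion, `alpha < 1` subdiffusion (confinement), `alpha > 1`
#' superdiffusion (drift).
#'
#' @param msd An `msd_curve` from [compute_msd()].
#' @param max_lag Optional cap on the number of lags used (e.g. `N/2`);
#'   default uses the entire curve.
#' @return List with `D_alpha` (um^2 s^-alpha), `alpha`, and `converged`.
#' @export
fit_alpha <- function(msd, max_lag = NULL) {
  stopifnot(inherits(msd, "msd_curve"))
  if (msd$N < 10L) stop("track too short for the power-law fit",
                        call. = FALSE)
  tv <- msd$lags; yv <- msd$msd
  if (!is.null(max_lag)) {
    keep <- seq_len(min(max_lag, length(tv)))
    tv <- tv[keep]; yv <- yv[keep]
  }
  d0 <- max(fit_d24(msd)$D_24, 1e-8)
  obj <- function(p) {       # p = (log D_alpha, alpha)
    resid <- yv - 4 * exp(p[1L]) * tv^p[2L]
    sum(resid * resid)
  }
  best <- NULL
  for (start in list(c(log(d0), 1),
                     c(log(d0), 0.5),
                     c(log(max(mean(yv) / (4 * mean(tv)), 1e-8)), 1.5))) {
    fit <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B",
                   lower = c(log(1e-12), 0), upper = c(log(1e6), 2),
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    return(list(D_alpha = NA_real_, alpha = NA_real_, converged = FALSE))
  list(D_alpha = exp(best$par[1L]), alpha = unname(best$par[2L]),
       converged = best$convergence == 0L)
}

#' Maximum-likelihood diffusion coefficient with noise and blur
#'
#' Estimates `D` by maximizing the exact Gaussian-process likelihood of
#' the observed displacement sequence. For a Brownian particle localized
#' with static error `sigma` and imaged with motion-blur coefficient `R`
#' (1/6 for full-frame continuous exposure), consecutive per-dimension
#' displacements are jointly Gaussian with
#' variance `2*D*dt + 2*sigma^2 - 4*R*D*dt` and lag-one covariance
#' `-(sigma^2 - 2*R*D*dt)`; all longer-range covariances vanish. The
#' resulting tridiagonal Toeplitz covariance is diagonalized by the
#' discrete sine transform, giving an O(N^2) exact likelihood (transform)
#' with O(N) evaluations inside the one-dimensional search over `D >= 0`.
#'
#' With `sigma = 0, R = 0` the estimate reduces to the closed form
#' `sum(|dr|^2) / (4 * n * dt)`.
#'
#' @param traj A reindexed [spt_track()].
#' @param loc_sigma Static localization error in um (default 0.025).
#' @param blur_R Motion-blur coefficient in `[0, 1/4]` (default 1/6).
#' @return List with `D_mle` (um^2/s, clamped at 0), `loc_sigma`, `blur_R`,
#'   `log_lik` and `clamped` (TRUE when the unconstrained optimum was
#'   negative).
#' @export
estimate_d_mle <- function(traj, loc_sigma = 0.025, blur_R = 1/6) {
  stopifnot(inherits(traj, "spt_track"))
  if (loc_sigma < 0) stop("loc_sigma must be >= 0", call. = FALSE)
  if (blur_R < 0 || blur_R > 0.25)
    stop("blur_R must be in [0, 1/4]", call. = FALSE)
  if (any(diff(traj$frame) != 1L))
    stop("trajectory has frame gaps: reindex_blink_gaps() first",
         call. = FALSE)
  dt <- track_dt(traj)
  dx <- diff(traj$x); dy <- diff(traj$y)
  n <- length(dx)
  # DST-II basis diagonalizes the tridiagonal Toeplitz covariance
  k <- seq_len(n)
  ck <- cos(k * pi / (n + 1L))
  M <- sqrt(2 / (n + 1L)) * sin(outer(seq_len(n), k) * pi / (n + 1L))
  wx <- drop(crossprod(M, dx)); wy <- drop(crossprod(M, dy))
  w2 <- wx * wx + wy * wy
  nll <- function(D) {
    a <- 2 * D * dt + 2 * loc_sigma^2 - 4 * blur_R * D * dt
    b <- 2 * blur_R * D * dt - loc_sigma^2
    lam <- a + 2 * b * ck
    if (any(lam <= 0)) return(Inf)
    sum(log(lam)) + 0.5 * sum(w2 / lam)
  }
  d_naive <- sum(w2) / (4 * n * dt)     # ||w|| = ||d||: orthogonal transform
  if (d_naive == 0) {
    if (loc_sigma == 0)
      stop("degenerate input: all displacements are zero and loc_sigma = 0",
           call. = FALSE)
    return(list(D_mle = 0, loc_sigma = loc_sigma, blur_R = blur_R,
                log_lik = -nll(0), clamped = TRUE))
  }
  # derivative of the negative log-likelihood in D (lambda is affine in D)
  dlam_dD <- 2 * dt * (1 - 2 * blur_R) + 4 * blur_R * dt * ck
  grad <- function(D) {
    a <- 2 * D * dt + 2 * loc_sigma^2 - 4 * blur_R * D * dt
    b <- 2 * blur_R * D * dt - loc_sigma^2
    lam <- a + 2 * b * ck
    sum(dlam_dD * (1 / lam - 0.5 * w2 / lam^2))
  }
  upper <- max(10 * d_naive, 1e-3)
  opt <- stats::optimize(nll, c(0, upper), tol = 1e-10)
  # polish with the analytic score for a reproducible, high-precision root
  lo <- max(opt$minimum / 2, upper * 1e-12)
  hi <- min(opt$minimum * 2, upper)
  if (is.finite(grad(lo)) && is.finite(grad(hi)) &&
      grad(lo) < 0 && grad(hi) > 0) {
    root <- stats::uniroot(grad, c(lo, hi), tol = 1e-15)$root
    if (is.finite(nll(root)) && nll(root) <= opt$objective)
      opt <- list(minimum = root, objective = nll(root))
  }
  # boundary solution at 0 means the unconstrained optimum is non-positive
  clamped <- opt$minimum < 1e-10 ||
    (is.finite(nll(0)) && nll(0) <= opt$objective)
  D_hat <- if (is.finite(nll(0)) && nll(0) <= opt$objective) 0
           else opt$minimum
  list(D_mle = D_hat, loc_sigma = loc_sigma, blur_R = blur_R,
       log_lik = -min(opt$objective, nll(0)), clamped = clamped && D_hat == 0)
}

#' Immobile classification from the MLE diffusion coefficient
#'
#' A track is called immobile when its `D_mle` falls strictly below the
#' threshold, by default `5e-4` um^2/s — the 95th percentile of the
#' `D_mle` null distribution measured on substrate-fixed emitters. The
#' threshold is configurable so it can be re-derived from a user's own
#' immobilized-control dataset via [immobile_threshold_from_null()].
#'
#' @param d_mle Numeric vector of MLE diffusion coefficients (um^2/s).
#' @param threshold Immobility cutoff in um^2/s.
#' @return Logical vector, TRUE = immobile.
#' @export
classify_immobile <- function(d_mle, threshold = 5e-4) {
  d_mle < threshold
}

#' Derive an immobility threshold from an immobilized-control null set
#'
#' @param d_mle_null `D_mle` values measured on immobilized emitters.
#' @param prob Percentile used as the cutoff (default 0.95).
#' @return The threshold in um^2/s.
#' @export
immobile_threshold_from_null <- function(d_mle_null, prob = 0.95) {
  stats::quantile(d_mle_null, prob, names = FALSE, type = 7)
}
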