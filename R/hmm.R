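#' Per-frame displacement sequence of a trajectory
#'
#' For a reindexed (contiguous-frame) track the instantaneous
#' displacements are `dr_t = r_{t+1} - r_t`. Under a diffusive state with
#' coefficient `D` each per-dimension displacement is Gaussian with
#' variance `2 * D * dt`; a drift `v` shifts the mean by `v * dt`. These
#' displacements are the observations the hidden Markov segmentation works
#' on.
#'
#' @param traj A reindexed [spt_track()].
#' @return An object of class `displacement_seq`: list with `dxy`
#'   (n x 2 matrix, um) and `dt` (s).
#' @export
displacements <- function(traj) {
  stopifnot(inherits(traj, "spt_track"))
  if (any(diff(traj$frame) != 1L))
    stop("trajectory has frame gaps: reindex_blink_gaps() first",
         call. = FALSE)
  structure(list(dxy = cbind(dx = diff(traj$x), dy = diff(traj$y)),
                 dt = track_dt(traj)),
            class = "displacement_seq")
}

#' Fit a Gaussian-displacement hidden Markov model
#'
#' Segments a displacement sequence into `K` diffusive states by
#' expectation-maximization (Baum-Welch). Emissions are isotropic 2D
#' Gaussians: state `k` has per-dimension variance `2 * D[k] * dt`
#' (plus an optional localization-noise floor `2 * loc_sigma^2`) and, in
#' the `"DV"` model, a per-state mean `v[k] * dt`. The best of
#' `n_restarts` EM runs by log-likelihood is returned; within each run the
#' log-likelihood is non-decreasing.
#'
#' @param seq A `displacement_seq` from [displacements()].
#' @param K Number of states (>= 1).
#' @param model `"D"` (pure diffusion, zero-mean emissions) or `"DV"`
#'   (diffusion plus per-state drift).
#' @param n_restarts Number of random EM initializations (default 10).
#' @param seed Optional integer seed.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   gain.
#' @param loc_sigma Optional localization-noise floor (um) added to the
#'   emission variance; 0 matches the bare diffusive emission model.
#' @return An object of class `hmm_fit`: `K`, `model`, `D` (um^2/s per
#'   state, sorted increasing), `v` (K x 2 matrix or NULL), `trans`
#'   (row-stochastic), `init`, `log_likelihood`, `loglik_trace`,
#'   `state_seq` (Viterbi path), `occupancy`, `n_params`, `bic`, `dt`.
#' @export
fit_hmm <- function(seq, K, model = c("D", "DV"), n_restarts = 10L,
                    seed = NULL, max_iter = 500L, tol = 1e-6,
                    loc_sigma = 0) {
  stopifnot(inherits(seq, "displacement_seq"))
  model <- match.arg(model)
  K <- as.integer(K)
  n <- nrow(seq$dxy)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (n < 10L * K)
    stop("sequence too short: need >= 10*K displacements", call. = FALSE)
  if (all(seq$dxy == 0))
    stop("degenerate input: all displacements are zero", call. = FALSE)
  .set_seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- .em_run(seq, K, model, jitter = r > 1L, max_iter = max_iter,
                   tol = tol, loc_sigma = loc_sigma)
    if (!is.null(fit) && (is.null(best) ||
                          fit$log_likelihood > best$log_likelihood))
      best <- fit
  }
  if (is.null(best)) stop("EM failed in all restarts", call. = FALSE)
  # order states by D for stable reporting
  ord <- order(best$D)
  best$D <- best$D[ord]
  if (!is.null(best$v)) best$v <- best$v[ord, , drop = FALSE]
  best$trans <- best$trans[ord, ord, drop = FALSE]
  best$init <- best$init[ord]
  best$state_seq <- decode_states(best, seq)
  best$occupancy <- tabulate(best$state_seq, K) / n
  best
}

# emission variance per dimension for state parameters
.emis_var <- function(D, dt, loc_sigma) 2 * D * dt + 2 * loc_sigma^2

# log emission density matrix (n x K), isotropic 2D Gaussian
.log_emis <- function(dxy, D, v, dt, loc_sigma) {
  n <- nrow(dxy); K <- length(D)
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    s2 <- max(.emis_var(D[k], dt, loc_sigma), 1e-12)
    mu <- if (is.null(v)) c(0, 0) else v[k, ] * dt
    out[, k] <- -log(2 * pi * s2) -
      ((dxy[, 1L] - mu[1L])^2 + (dxy[, 2L] - mu[2L])^2) / (2 * s2)
  }
  out
}

.em_run <- function(seq, K, model, jitter, max_iter, tol, loc_sigma) {
  dxy <- seq$dxy; dt <- seq$dt; n <- nrow(dxy)
  # init: split displacements by quantile bins of |dr|^2
  r2 <- rowSums(dxy^2)
  br <- stats::quantile(r2, probs = seq(0, 1, length.out = K + 1L),
                        type = 7)
  br[1L] <- -Inf; br[K + 1L] <- Inf
  bin <- cut(r2, breaks = unique(br), labels = FALSE)
  if (length(unique(bin)) < K) bin <- ((seq_len(n) - 1L) %% K) + 1L
  D <- vapply(seq_len(K), function(k) {
    m <- mean(r2[bin == k])
    max((m / 4 - loc_sigma^2) / dt, 1e-8)
  }, numeric(1))
  if (jitter) D <- D * exp(stats::rnorm(K, sd = 0.5))
  v <- if (model == "DV") {
    vv <- matrix(0, K, 2L)
    if (jitter) vv <- vv + matrix(stats::rnorm(2L * K,
                                               sd = stats::sd(dxy) / dt / 10),
                                  K, 2L)
    vv
  } else NULL
  trans <- matrix(0.1 / max(K - 1L, 1L), K, K)
  diag(trans) <- if (K > 1L) 0.9 else 1
  init <- rep(1 / K, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logB <- .log_emis(dxy, D, v, dt, loc_sigma)
    fb <- .forward_backward(logB, trans, init)
    ll <- fb$log_lik
    ll_trace <- c(ll_trace, ll)
    if (!is.finite(ll)) return(NULL)
    g <- fb$gamma
    # M-step
    init <- g[1L, ]
    if (K > 1L) {
      xi <- fb$xi_sum
      rs <- rowSums(xi)
      rs[rs == 0] <- 1
      trans <- xi / rs
    }
    for (k in seq_len(K)) {
      wk <- g[, k]; sw <- sum(wk)
      if (sw <= 0) next
      mu <- if (model == "DV") colSums(dxy * wk) / sw else c(0, 0)
      s2 <- sum(wk * ((dxy[, 1L] - mu[1L])^2 +
                        (dxy[, 2L] - mu[2L])^2)) / (2 * sw)
      D[k] <- max((s2 - 2 * loc_sigma^2) / (2 * dt), 1e-10)
      if (model == "DV") v[k, ] <- mu / dt
    }
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  n_params <- (K - 1L) + K * (K - 1L) + K + (if (model == "DV") 2L * K else 0L)
  structure(list(K = K, model = model, D = D, v = v, trans = trans,
                 init = init, log_likelihood = ll,
                 loglik_trace = ll_trace, n_params = n_params,
                 bic = -2 * ll + n_params * log(n), dt = dt,
                 loc_sigma = loc_sigma),
            class = "hmm_fit")
}

# scaled forward-backward; returns gamma (n x K), summed xi (K x K), loglik
.forward_backward <- function(logB, trans, init) {
  n <- nrow(logB); K <- ncol(logB)
  Bmax <- apply(logB, 1L, max)
  B <- exp(logB - Bmax)
  alpha <- matrix(0, n, K); beta <- matrix(0, n, K)
  cvec <- numeric(n)
  a <- init * B[1L, ]
  cvec[1L] <- sum(a)
  alpha[1L, ] <- a / cvec[1L]
  if (n > 1L) for (t in 2:n) {
    a <- drop(alpha[t - 1L, ] %*% trans) * B[t, ]
    cvec[t] <- sum(a)
    if (cvec[t] <= 0) return(list(log_lik = -Inf))
    alpha[t, ] <- a / cvec[t]
  }
  beta[n, ] <- 1
  if (n > 1L) for (t in (n - 1L):1L) {
    b <- drop(trans %*% (B[t + 1L, ] * beta[t + 1L, ]))
    beta[t, ] <- b / cvec[t + 1L]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  if (n > 1L) for (t in seq_len(n - 1L)) {
    xi <- (alpha[t, ] %o% (B[t + 1L, ] * beta[t + 1L, ])) * trans /
      cvec[t + 1L]
    xi_sum <- xi_sum + xi
  }
  list(gamma = gamma, xi_sum = xi_sum,
       log_lik = sum(log(cvec)) + sum(Bmax))
}

#' Viterbi decoding of the diffusive-state path
#'
#' Returns the single most probable hidden-state sequence under a fitted
#' model, one label per displacement.
#'
#' @param fit An `hmm_fit`.
#' @param seq The `displacement_seq` the model was fitted to.
#' @return Integer vector of state labels in `1..K`.
#' @export
decode_states <- function(fit, seq) {
  stopifnot(inherits(fit, "hmm_fit"), inherits(seq, "displacement_seq"))
  logB <- .log_emis(seq$dxy, fit$D, fit$v, seq$dt, fit$loc_sigma)
  n <- nrow(logB); K <- ncol(logB)
  logA <- log(pmax(fit$trans, 1e-300))
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1L, ] <- log(pmax(fit$init, 1e-300)) + logB[1L, ]
  if (n > 1L) for (t in 2:n) {
    for (k in seq_len(K)) {
      cand <- delta[t - 1L, ] + logA[, k]
      psi[t, k] <- which.max(cand)
      delta[t, k] <- cand[psi[t, k]] + logB[t, k]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Select the number of diffusive states and emission model by BIC
#'
#' Fits every candidate model (`K = 1..K_max` crossed with the requested
#' emission forms) and returns the fit minimizing the Bayesian information
#' criterion, a deterministic stand-in for full Bayesian model-class
#' evidence over the same Gaussian-displacement family.
#'
#' @param seq A `displacement_seq`.
#' @param K_max Largest state count considered (default 3).
#' @param models Emission forms to consider (`"D"`, `"DV"`).
#' @param n_restarts,seed,loc_sigma Passed to [fit_hmm()].
#' @return The winning `hmm_fit`, with a `selection` data frame (K, model,
#'   log_likelihood, n_params, bic) for every candidate attached.
#' @export
select_hmm_model <- function(seq, K_max = 3L, models = c("D", "DV"),
                             n_restarts = 10L, seed = NULL, loc_sigma = 0) {
  stopifnot(inherits(seq, "displacement_seq"))
  if (K_max < 1L) stop("K_max must be >= 1", call. = FALSE)
  .set_seed(seed)
  fits <- list()
  rows <- list()
  for (model in models) for (K in seq_len(K_max)) {
    fit <- tryCatch(
      fit_hmm(seq, K, model = model, n_restarts = n_restarts,
              loc_sigma = loc_sigma),
      error = function(e) NULL)
    if (is.null(fit)) next
    key <- paste0(model, K)
    fits[[key]] <- fit
    rows[[key]] <- data.frame(K = K, model = model,
                              log_likelihood = fit$log_likelihood,
                              n_params = fit$n_params, bic = fit$bic)
  }
  if (!length(fits)) stop("no candidate model could be fitted", call. = FALSE)
  sel <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "bic"))]]
  best$selection <- sel
  best
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> K = %d, model = %s, logLik = %.2f, BIC = %.2f\n",
              x$K, x$model, x$log_likelihood, x$bic))
  cat("  D (um^2/s):", paste(signif(x$D, 3), collapse = ", "), "\n")
  if (!is.null(x$v))
    cat("  v (um/s):",
        paste(apply(signif(x$v, 3), 1L, paste, collapse = "/"),
              collapse = ", "), "\n")
  if (!is.null(x$occupancy))
    cat("  occupancy:", paste(signif(x$occupancy, 3), collapse = ", "), "\n")
  invisible(x)
}
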