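#' Median / interquartile summary of a metric within a group
#'
#' Diffusion metrics are heavy-tailed, so groups are summarised as median
#' with the 25-75% interquartile interval (linear interpolation between
#' order statistics, quantile type 7 — recorded because the interval
#' depends on the convention).
#'
#' @param values Numeric vector (non-finite values dropped).
#' @param label Group label.
#' @param metric Metric name.
#' @return Data frame with `group`, `metric`, `median`, `q25`, `q75`, `N`.
#' @export
summarize_group <- function(values, label = "group", metric = "value") {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values to summarize", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  data.frame(group = label, metric = metric, median = q[2L],
             q25 = q[1L], q75 = q[3L], N = length(values))
}

#' Nonparametric two-sample comparison of metric distributions
#'
#' Pairwise comparison of two groups' metric distributions with either the
#' Mann-Whitney U test (`stats::wilcox.test`: exact for small tie-free
#' samples, normal approximation with tie correction otherwise) or the
#' two-sample Kolmogorov-Smirnov test. Two-sided throughout; significance
#' is called at `alpha = 0.01`.
#'
#' @param a,b Numeric vectors (non-finite values dropped).
#' @param test `"mann_whitney"` or `"ks"`.
#' @param alpha Significance level.
#' @return Data frame with `test`, `p_value`, `significant`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, test = c("mann_whitney", "ks"),
                           alpha = 0.01) {
  test <- match.arg(test)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b))
    stop("both groups must be non-empty", call. = FALSE)
  p <- if (test == "mann_whitney")
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  else
    suppressWarnings(stats::ks.test(a, b)$p.value)
  data.frame(test = test, p_value = p, significant = p < alpha,
             n_a = length(a), n_b = length(b))
}

#' Per-track diffusion and geometry metrics table
#'
#' Computes the standard per-trajectory quantities for every track in a
#' set: length, `D_mle` (noise/blur-aware MLE), short-lag `D_24` and
#' offset, anomalous exponent `alpha` and `D_alpha`, bounding-box aspect
#' ratio, explored area, and the immobile flag.
#'
#' @param ts An [spt_trackset()] of reindexed tracks.
#' @param loc_sigma,blur_R Passed to [estimate_d_mle()].
#' @param immobile_threshold Immobility cutoff (um^2/s).
#' @return Data frame, one row per track.
#' @export
track_metrics <- function(ts, loc_sigma = 0.025, blur_R = 1/6,
                          immobile_threshold = 5e-4) {
  stopifnot(inherits(ts, "spt_trackset"))
  rows <- lapply(ts$tracks, function(tr) {
    msd <- compute_msd(tr)
    d24 <- fit_d24(msd)
    al <- fit_alpha(msd)
    dm <- estimate_d_mle(tr, loc_sigma = loc_sigma, blur_R = blur_R)
    ar <- suppressWarnings(aspect_ratio(tr))
    ea <- suppressWarnings(explored_area(tr))
    data.frame(track_id = track_id(tr), N = nrow(tr), D_mle = dm$D_mle,
               D_24 = d24$D_24, offset = d24$offset, alpha = al$alpha,
               D_alpha = al$D_alpha, aspect_ratio = as.numeric(ar),
               explored_area = ea,
               immobile = classify_immobile(dm$D_mle, immobile_threshold))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Run the full trajectory-analysis pipeline
#'
#' Composes the standard analysis end to end: reindex blink gaps (tracks
#' with longer gaps are split), drop tracks shorter than `min_frames`,
#' compute per-track metrics, flag immobile tracks, classify the mobile
#' ones as restricted/free by relative deviation, and summarise. Every
#' input track ends in exactly one terminal category: `too_short`,
#' `immobile`, `unclassifiable`, `restricted` or `free`. The run is
#' deterministic given inputs and configuration.
#'
#' @param ts An [spt_trackset()].
#' @param calib An `rd_calibration` (required for classification).
#' @param loc_sigma,blur_R,immobile_threshold,min_frames,n_lag
#'   Analysis parameters; see [estimate_d_mle()], [classify_immobile()],
#'   [filter_min_length()], [compute_rd()].
#' @return List with `metrics` (per-track table including `label`),
#'   `fractions` (per terminal category, over all input tracks), and
#'   `log` (stage counts).
#' @export
run_pipeline <- function(ts, calib, loc_sigma = 0.025, blur_R = 1/6,
                         immobile_threshold = 5e-4, min_frames = 50L,
                         n_lag = 25L) {
  stopifnot(inherits(ts, "spt_trackset"))
  if (missing(calib) || !inherits(calib, "rd_calibration"))
    stop("an rd_calibration is required for motion classification",
         call. = FALSE)
  n_read <- length(ts$tracks)
  split_tracks <- unlist(lapply(ts$tracks, split_long_gaps),
                         recursive = FALSE)
  ts2 <- spt_trackset(unname(split_tracks), dt = ts$dt,
                      loc_sigma = ts$loc_sigma, source = ts$source)
  ts2$tracks <- lapply(ts2$tracks, reindex_blink_gaps)
  kept <- filter_min_length(ts2, min_frames, quiet = TRUE)
  n_short <- length(ts2$tracks) - length(kept$tracks)
  if (length(kept$tracks) == 0L) {
    warning("no tracks of at least ", min_frames, " frames: empty result",
            call. = FALSE)
    log <- c(read = n_read, after_split = length(ts2$tracks),
             too_short = n_short, analyzed = 0L)
    return(list(metrics = NULL, fractions = c(too_short = 1),
                log = log))
  }
  metrics <- track_metrics(kept, loc_sigma = loc_sigma, blur_R = blur_R,
                           immobile_threshold = immobile_threshold)
  cls <- classify_trackset(kept, calib, loc_sigma = loc_sigma,
                           blur_R = blur_R,
                           immobile_threshold = immobile_threshold,
                           n_lag = n_lag)
  metrics$rd <- cls$per_track$rd[match(metrics$track_id,
                                       cls$per_track$track_id)]
  metrics$label <- cls$per_track$label[match(metrics$track_id,
                                             cls$per_track$track_id)]
  n_total <- length(ts2$tracks)
  tab <- table(factor(metrics$label,
                      levels = c("immobile", "restricted", "free",
                                 "unclassifiable")))
  fractions <- c(too_short = n_short, as.numeric(tab))
  names(fractions) <- c("too_short", names(tab))
  fractions <- fractions / n_total
  log <- c(read = n_read, after_split = n_total, too_short = n_short,
           analyzed = length(kept$tracks), immobile = unname(tab["immobile"]),
           restricted = unname(tab["restricted"]), free = unname(tab["free"]),
           unclassifiable = unname(tab["unclassifiable"]))
  list(metrics = metrics, fractions = fractions, log = log)
}

#' Write a group report in tabular form
#'
#' Emits the per-group summary table (group, metric, median, q25, q75, N)
#' and, optionally, a pairwise-comparison table, as TSV files.
#'
#' @param summaries Data frame of stacked [summarize_group()] rows.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
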