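#' Construct a single trajectory
#'
#' A trajectory is the atom of every computation in this package: one
#' particle's time-ordered 2D positions. It is stored as a data frame with
#' columns `frame` (0-based integer indices, strictly increasing), `t`
#' (seconds), `x` and `y` (micrometres), carrying the track identifier and
#' the nominal frame interval `dt` as attributes.
#'
#' @param x,y Numeric coordinates in micrometres.
#' @param frame Integer frame indices, 0-based and strictly increasing.
#' @param dt Nominal frame interval in seconds.
#' @param track_id Track identifier (coerced to character).
#' @param t Optional time stamps in seconds; rebuilt as `frame * dt` when
#'   missing.
#' @return An object of class `spt_track` (a data frame).
#' @examples
#' tr <- spt_track(x = c(0, 1, 1), y = c(0, 0, 1), dt = 0.1)
#' track_dt(tr)
#' @export
spt_track <- function(x, y, frame = seq_along(x) - 1L, dt = 0.1,
                      track_id = "1", t = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  frame <- as.integer(frame)
  n <- length(x)
  if (n < 2L || length(y) != n || length(frame) != n)
    stop("a trajectory needs >= 2 points with matching x, y and frame lengths",
         call. = FALSE)
  if (any(diff(frame) <= 0L))
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  if (is.null(t)) t <- frame * dt
  out <- data.frame(frame = frame, t = as.numeric(t), x = x, y = y)
  attr(out, "track_id") <- as.character(track_id)
  attr(out, "dt") <- dt
  class(out) <- c("spt_track", "data.frame")
  out
}

#' @rdname spt_track
#' @param traj An `spt_track` object.
#' @export
track_dt <- function(traj) attr(traj, "dt")

#' @rdname spt_track
#' @export
track_id <- function(traj) attr(traj, "track_id")

#' Construct a set of trajectories
#'
#' Bundles trajectories with acquisition metadata (nominal frame interval,
#' localization-noise scale, a free-form source label). Track identifiers
#' must be unique.
#'
#' @param tracks A list of [spt_track()] objects.
#' @param dt Nominal frame interval in seconds (defaults to the first
#'   track's).
#' @param loc_sigma Static localization error in micrometres (metadata only).
#' @param source Free-form label recording where the tracks came from.
#' @return An object of class `spt_trackset`.
#' @export
spt_trackset <- function(tracks, dt = NULL, loc_sigma = NA_real_,
                         source = NA_character_) {
  stopifnot(is.list(tracks))
  ids <- vapply(tracks, track_id, character(1))
  if (anyDuplicated(ids))
    stop("track ids must be unique", call. = FALSE)
  names(tracks) <- ids
  if (is.null(dt)) dt <- if (length(tracks)) track_dt(tracks[[1L]]) else NA_real_
  structure(list(tracks = tracks, dt = dt, loc_sigma = loc_sigma,
                 source = source),
            class = "spt_trackset")
}

#' @export
length.spt_trackset <- function(x) length(x$tracks)

#' @export
print.spt_trackset <- function(x, ...) {
  n <- length(x$tracks)
  lens <- vapply(x$tracks, nrow, integer(1))
  cat(sprintf("<spt_trackset> %d track(s), dt = %s s", n,
              format(x$dt)), "\n")
  if (n) cat(sprintf("  track length: %d-%d frames (median %d)\n",
                     min(lens), max(lens), as.integer(stats::median(lens))))
  invisible(x)
}

#' @export
print.spt_track <- function(x, ...) {
  cat(sprintf("<spt_track> id = %s, %d points, dt = %s s\n",
              track_id(x), nrow(x), format(track_dt(x))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read trajectories from a delimited file
#'
#' Reads the canonical track table: columns `track_id`, `frame`, `x`, `y`
#' and optionally `t`, comma- or tab-separated (sniffed from the header
#' line). Coordinates in pixel units are converted to micrometres with
#' `pixel_size` (0.22 um/pixel by default, a common EMCCD calibration).
#' Rows are grouped by `track_id` and sorted by `frame`; duplicated frames
#' within a track keep the first occurrence with a warning.
#'
#' @param path Path to a CSV/TSV file.
#' @param units Either `"um"` (default) or `"pixel"`.
#' @param pixel_size Pixel size in micrometres, used when `units = "pixel"`.
#' @param dt Nominal frame interval in seconds; used to rebuild missing `t`.
#' @return An [spt_trackset()].
#' @export
read_tracks <- function(path, units = c("um", "pixel"), pixel_size = 0.22,
                        dt = 0.1) {
  units <- match.arg(units)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    warning("empty track file: ", path, call. = FALSE)
    return(spt_trackset(list(), dt = dt, source = path))
  }
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "x", "y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("track file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) {
    warning("track file has a header but no rows: ", path, call. = FALSE)
    return(spt_trackset(list(), dt = dt, source = path))
  }
  scale <- if (units == "pixel") pixel_size else 1
  tracks <- lapply(split(df, as.character(df$track_id)), function(g) {
    g <- g[order(g$frame), , drop = FALSE]
    dup <- duplicated(g$frame)
    if (any(dup)) {
      warning(sprintf("track %s: %d duplicated frame(s) dropped (first kept)",
                      g$track_id[1L], sum(dup)), call. = FALSE)
      g <- g[!dup, , drop = FALSE]
    }
    if (any(diff(g$frame) <= 0))
      stop("non-monotone frames within track ", g$track_id[1L], call. = FALSE)
    spt_track(x = g$x * scale, y = g$y * scale,
              frame = g$frame, dt = dt, track_id = g$track_id[1L],
              t = if ("t" %in% names(g)) g$t else NULL)
  })
  spt_trackset(unname(tracks), dt = dt, source = path)
}

#' Write trajectories to CSV
#'
#' Emits the canonical schema `track_id,frame,t,x,y` (coordinates in
#' micrometres, frames 0-based) so that `read_tracks()` round-trips the set.
#'
#' @param ts An [spt_trackset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "spt_trackset"))
  df <- as.data.frame(ts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.spt_trackset <- function(x, ...) {
  if (!length(x$tracks))
    return(data.frame(track_id = character(), frame = integer(),
                      t = numeric(), x = numeric(), y = numeric()))
  do.call(rbind, c(lapply(x$tracks, function(tr) {
    data.frame(track_id = track_id(tr), frame = tr$frame, t = tr$t,
               x = tr$x, y = tr$y, row.names = NULL)
  }), list(make.row.names = FALSE)))
}

#' Close blink gaps by reindexing a trajectory
#'
#' Fluorophore blinking leaves missing frames inside a track. Downstream
#' MSD analysis assumes a regular time grid, so gaps of at most `max_gap`
#' frames are closed by remapping the surviving frames to consecutive
#' indices `0..n-1` and rebuilding `t = frame * dt`. Positions are left
#' untouched and the original frame indices are retained as the
#' `"orig_frames"` attribute. Gaps longer than `max_gap` indicate distinct
#' detections and are an error: split the track instead.
#'
#' The operation is idempotent.
#'
#' @param traj An [spt_track()].
#' @param max_gap Largest permissible run of missing frames (default 10,
#'   the continuity window used when linking blinking emitters).
#' @return The reindexed `spt_track`.
#' @export
reindex_blink_gaps <- function(traj, max_gap = 10L) {
  stopifnot(inherits(traj, "spt_track"))
  gaps <- diff(traj$frame) - 1L
  if (any(gaps > max_gap))
    stop(sprintf(
      "track %s has a gap of %d missing frames (> %d): split it into separate tracks before reindexing",
      track_id(traj), max(gaps), max_gap), call. = FALSE)
  orig <- attr(traj, "orig_frames")
  if (is.null(orig)) orig <- traj$frame
  out <- spt_track(x = traj$x, y = traj$y,
                   frame = seq_len(nrow(traj)) - 1L,
                   dt = track_dt(traj), track_id = track_id(traj))
  attr(out, "orig_frames") <- orig
  out
}

#' Split a trajectory at long blink gaps
#'
#' Runs of more than `max_gap` missing frames mean the linker should have
#' treated the detections as separate tracks; this helper performs that
#' split, appending `.1`, `.2`, ... to the track id. Segments shorter than
#' 2 points are dropped.
#'
#' @inheritParams reindex_blink_gaps
#' @return A list of `spt_track` objects.
#' @export
split_long_gaps <- function(traj, max_gap = 10L) {
  stopifnot(inherits(traj, "spt_track"))
  cut <- which(diff(traj$frame) - 1L > max_gap)
  if (!length(cut)) return(list(traj))
  seg <- findInterval(seq_len(nrow(traj)), cut + 1L) + 1L
  parts <- split(seq_len(nrow(traj)), seg)
  out <- list()
  for (k in seq_along(parts)) {
    idx <- parts[[k]]
    if (length(idx) < 2L) next
    out[[length(out) + 1L]] <-
      spt_track(x = traj$x[idx], y = traj$y[idx], frame = traj$frame[idx],
                dt = track_dt(traj),
                track_id = paste0(track_id(traj), ".", k))
  }
  out
}

#' Drop trajectories shorter than a minimum length
#'
#' Short tracks yield noisy MSD statistics; the standard filter keeps only
#' trajectories with at least `min_frames` localizations (default 50).
#'
#' @param ts An [spt_trackset()].
#' @param min_frames Minimum number of points a track must have.
#' @param quiet Suppress the removal message.
#' @return The filtered [spt_trackset()].
#' @export
filter_min_length <- function(ts, min_frames = 50L, quiet = FALSE) {
  stopifnot(inherits(ts, "spt_trackset"))
  keep <- vapply(ts$tracks, nrow, integer(1)) >= min_frames
  if (!quiet && any(!keep))
    message(sum(!keep), " track(s) shorter than ", min_frames,
            " frames removed")
  spt_trackset(unname(ts$tracks[keep]), dt = ts$dt,
               loc_sigma = ts$loc_sigma, source = ts$source)
}
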