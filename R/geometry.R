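#' Aspect ratio of the minimum-area bounding box of a trajectory
#'
#' Computes the minimum-area rotated rectangle enclosing the track's point
#' set (rotating calipers over the convex hull: the optimal rectangle has
#' one side collinear with a hull edge) and returns the ratio of its longer
#' to shorter side. A value near 1 indicates an isotropic blob; elongated
#' tracks (e.g. along a membrane protrusion) score higher. The metric is
#' invariant under translation and rotation of the track.
#'
#' Collinear point sets have zero width: the ratio is then reported against
#' a 1e-6 um width floor and flagged degenerate; fully coincident point
#' sets return `NA` with the degenerate flag set.
#'
#' @param traj An [spt_track()] with at least 3 points.
#' @return Numeric aspect ratio (>= 1) with attribute `degenerate`
#'   (logical).
#' @export
aspect_ratio <- function(traj) {
  stopifnot(inherits(traj, "spt_track"))
  if (nrow(traj) < 3L) stop("aspect ratio needs >= 3 points", call. = FALSE)
  p <- unique(cbind(traj$x, traj$y))
  if (nrow(p) == 1L)
    return(structure(NA_real_, degenerate = TRUE))
  box <- .min_area_box(p)
  degenerate <- box$short < 1e-6
  ratio <- box$long / max(box$short, 1e-6)
  structure(ratio, degenerate = degenerate)
}

# minimum-area rotated bounding rectangle: for each convex-hull edge,
# project all hull points onto the edge direction and its normal
.min_area_box <- function(p) {
  h <- grDevices::chull(p)
  hp <- p[h, , drop = FALSE]
  m <- nrow(hp)
  if (m == 1L) return(list(long = 0, short = 0))
  if (m == 2L) {
    d <- sqrt(sum((hp[2L, ] - hp[1L, ])^2))
    return(list(long = d, short = 0))
  }
  best <- NULL
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    len <- sqrt(sum(e * e))
    if (len == 0) next
    u <- e / len; v <- c(-u[2L], u[1L])
    a <- hp %*% u; b <- hp %*% v
    w1 <- max(a) - min(a); w2 <- max(b) - min(b)
    area <- w1 * w2
    if (is.null(best) || area < best$area)
      best <- list(area = area, long = max(w1, w2), short = min(w1, w2))
  }
  best
}

#' Explored area of a trajectory
#'
#' Area of the convex hull over the entire trajectory, normalized to the
#' number of time points (um^2 per point) — a per-frame measure of the
#' territory a particle covers over the recording. Collinear tracks have
#' zero hull area and return 0 with a warning.
#'
#' @param traj An [spt_track()] with at least 3 points.
#' @return Explored area in um^2 per time point.
#' @export
explored_area <- function(traj) {
  stopifnot(inherits(traj, "spt_track"))
  N <- nrow(traj)
  if (N < 3L) stop("explored area needs >= 3 points", call. = FALSE)
  a <- convex_hull_area(cbind(traj$x, traj$y))
  if (a == 0) warning("degenerate (collinear) trajectory: hull area 0",
                      call. = FALSE)
  a / N
}

#' Convex-hull area of a 2D point set
#'
#' @param p Two-column matrix of coordinates.
#' @return Hull area (shoelace formula over `grDevices::chull()`).
#' @export
convex_hull_area <- function(p) {
  p <- unique(p)
  if (nrow(p) < 3L) return(0)
  h <- grDevices::chull(p)
  hp <- p[h, , drop = FALSE]
  x <- hp[, 1L]; y <- hp[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}
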