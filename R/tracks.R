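#' Body elongation and axis from a point cloud
#'
#' Fits an ellipse to a set of 2-D body points via the second central moment
#' (inertia) matrix. The body axis is the principal eigenvector and the
#' elongation is \code{2 * sqrt(lambda_max)}; any fixed positive
#' proportionality constant is equivalent downstream because only the
#' relative elongation (instantaneous over track mean) enters the model.
#'
#' @param points numeric matrix (n x 2) of coordinates in mm, n >= 3.
#' @return list with \code{elongation} (mm), \code{axis} (unit 2-vector) and
#'   \code{degenerate} (TRUE when the two eigenvalues are equal, i.e. an
#'   isotropic cloud where the axis direction is arbitrary).
#' @examples
#' pts <- cbind(seq(-0.5, 0.5, length.out = 21), 0)
#' elongation_from_points(pts)$elongation  # L/sqrt(3) for a uniform rod
#' @export
elongation_from_points <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L || ncol(points) != 2L)
    stop("need at least 3 two-dimensional points")
  stop_if_not_finite(points, "points")
  ctr <- sweep(points, 2L, colMeans(points))
  M <- crossprod(ctr) / nrow(ctr)  # second central moment matrix
  e <- eigen(M, symmetric = TRUE)
  lam <- e$values
  degenerate <- isTRUE(all.equal(lam[1L], lam[2L],
                                 tolerance = 1e-8,
                                 scale = max(lam[1L], .Machine$double.eps)))
  axis <- e$vectors[, 1L]
  axis <- axis / sqrt(sum(axis^2))
  list(elongation = 2 * sqrt(lam[1L]), axis = axis, degenerate = degenerate)
}

#' Construct a worm track
#'
#' Per-frame kinematic and shape observations for one animal: centroid
#' position (mm), body-axis unit vector (sign arbitrary frame to frame) and
#' body elongation (mm), sampled at a uniform frame interval.
#'
#' @param track_id identifier.
#' @param time_s strictly increasing times with constant step (s).
#' @param x_mm,y_mm centroid coordinates (mm).
#' @param axis_x,axis_y body-axis unit-vector components.
#' @param elongation_mm body elongation per frame (mm), positive.
#' @param censored_start,censored_end whether the track begins/ends because
#'   the animal was lost (TRUE, the default for real recordings) rather than
#'   at assay boundaries.
#' @return object of class \code{worm_track} (a data frame plus metadata).
#' @export
worm_track <- function(track_id, time_s, x_mm, y_mm, axis_x, axis_y,
                       elongation_mm, censored_start = TRUE,
                       censored_end = TRUE) {
  n <- length(time_s)
  stopifnot(length(x_mm) == n, length(y_mm) == n, length(axis_x) == n,
            length(axis_y) == n, length(elongation_mm) == n, n >= 2L)
  dt <- diff(time_s)
  if (any(dt <= 0)) stop("time_s must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("time_s must have a uniform frame interval")
  nrm <- sqrt(axis_x^2 + axis_y^2)
  if (any(abs(nrm - 1) > 1e-6))
    stop("body-axis vectors must have unit length (within 1e-6)")
  if (any(elongation_mm <= 0)) stop("elongation_mm must be positive")
  out <- data.frame(track_id = track_id, time_s = time_s, x_mm = x_mm,
                    y_mm = y_mm, axis_x = axis_x, axis_y = axis_y,
                    elongation_mm = elongation_mm)
  structure(out, class = c("worm_track", "data.frame"),
            dt = mean(dt), censored_start = isTRUE(censored_start),
            censored_end = isTRUE(censored_end))
}

#' @export
print.worm_track <- function(x, ...) {
  cat(sprintf("<worm_track> id=%s, %d frames, dt=%.3g s, span %.1f s\n",
              x$track_id[1L], nrow(x), attr(x, "dt"),
              x$time_s[nrow(x)] - x$time_s[1L]))
  invisible(x)
}

#' Observation series for state inference
#'
#' Reduces a track to the two observables the state model uses: the relative
#' elongation \code{r} (instantaneous elongation over its track mean, so
#' \code{mean(r) == 1} by construction) and the signed displacement \code{dx}
#' obtained by projecting the frame-to-frame centroid displacement onto the
#' body axis. Because the head/tail orientation of the axis is unknown, the
#' axis sign is propagated for continuity: whenever a frame's axis has a
#' negative dot product with the previous (sign-corrected) axis it is
#' flipped, so the relation between the sign of \code{dx} and the direction
#' of movement stays consistent along the track. Which sign corresponds to
#' forward movement is left to the state inference.
#'
#' @param track a \code{worm_track}.
#' @return object of class \code{observation_series}: list with \code{r}
#'   (length n), \code{dx} (length n - 1, mm), \code{dt} (s), and the
#'   sign-corrected axis matrix.
#' @export
preprocess_track <- function(track) {
  stopifnot(inherits(track, "worm_track"))
  n <- nrow(track)
  ax <- cbind(track$axis_x, track$axis_y)
  for (t in 2:n) {
    if (sum(ax[t, ] * ax[t - 1L, ]) < 0) ax[t, ] <- -ax[t, ]
  }
  r <- track$elongation_mm / mean(track$elongation_mm)
  dpos <- cbind(diff(track$x_mm), diff(track$y_mm))
  dx <- rowSums(dpos * ax[-n, , drop = FALSE])
  structure(list(r = r, dx = dx, dt = attr(track, "dt"), axis = ax,
                 track_id = track$track_id[1L],
                 censored_start = attr(track, "censored_start"),
                 censored_end = attr(track, "censored_end")),
            class = "observation_series")
}
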