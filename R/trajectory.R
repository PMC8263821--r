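#' Trajectory container
#'
#' An ordered sequence of planar GPS fixes with per-step durations.  All
#' coordinates are metres in a planar projection and durations are minutes;
#' the first duration is always 0 (nothing precedes the first fix).
#'
#' @param x,y numeric vectors of coordinates (metres).
#' @param dt per-step durations in minutes; `dt[1]` must be 0 (it is forced
#'   to 0 when omitted).  Defaults to a constant 10-minute interval.
#' @param id optional animal identifier.
#' @return An object of class `bcr_trajectory`: a list with elements `x`,
#'   `y`, `dt` and `id`.
#' @examples
#' tr <- bcr_trajectory(c(0, 30, 60), c(0, 0, 20))
#' step_lengths(tr)
#' @export
bcr_trajectory <- function(x, y, dt = NULL, id = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stopf("x and y must have the same length")
  if (n < 1) stopf("a trajectory needs at least one fix")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stopf("coordinates must be finite")
  if (is.null(dt)) dt <- c(0, rep(10, n - 1))
  dt <- as.numeric(dt)
  if (length(dt) != n) stopf("dt must have one duration per fix")
  dt[1] <- 0
  if (n > 1 && any(dt[-1] < 0)) stopf("durations must be non-negative")
  structure(list(x = x, y = y, dt = dt, id = id), class = "bcr_trajectory")
}

as_trajectory <- function(obj) {
  if (inherits(obj, "bcr_trajectory")) return(obj)
  if (is.matrix(obj) || is.data.frame(obj)) {
    obj <- as.data.frame(obj)
    if (all(c("x", "y") %in% names(obj)))
      return(bcr_trajectory(obj$x, obj$y, obj$dt))
    return(bcr_trajectory(obj[[1]], obj[[2]]))
  }
  stopf("cannot interpret object of class '%s' as a trajectory",
        paste(class(obj), collapse = "/"))
}

#' @export
print.bcr_trajectory <- function(x, ...) {
  n <- length(x$x)
  cat(sprintf("<bcr_trajectory%s: %d fixes, %.1f min, path %.1f m>\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              n, sum(x$dt), path_length(x)))
  invisible(x)
}

#' @export
as.data.frame.bcr_trajectory <- function(x, ...) {
  data.frame(t = cumsum(x$dt), x = x$x, y = x$y)
}

#' @rdname bcr_trajectory
#' @param traj a [bcr_trajectory()].
#' @export
n_fixes <- function(traj) length(traj$x)

#' Step lengths, headings and turning angles of a trajectory
#'
#' `step_lengths()` returns the `n - 1` Euclidean displacements between
#' successive fixes. `step_headings()` returns the absolute heading of each
#' step (`NA` for zero-length steps). `turning_angles()` returns the `n - 2`
#' relative turning angles (counter-clockwise positive, 0 = straight ahead;
#' `NA` where either leg has zero length).
#'
#' @param traj a [bcr_trajectory()].
#' @return A numeric vector.
#' @export
step_lengths <- function(traj) {
  sqrt(diff(traj$x)^2 + diff(traj$y)^2)
}

#' @rdname step_lengths
#' @export
step_headings <- function(traj) {
  dx <- diff(traj$x)
  dy <- diff(traj$y)
  h <- atan2(dy, dx)
  h[dx == 0 & dy == 0] <- NA_real_
  h
}

#' @rdname step_lengths
#' @export
turning_angles <- function(traj) {
  h <- step_headings(traj)
  n <- length(h)
  if (n < 2) return(numeric(0))
  wrap_angle(h[-1] - h[-n])
}

#' @rdname step_lengths
#' @export
path_length <- function(traj) sum(step_lengths(traj))

#' Absolute heading from one point to another
#'
#' Four-quadrant inverse tangent of the displacement, in `(-pi, pi]`.
#'
#' @param a,b points as length-2 numeric vectors `(x, y)`.
#' @return Heading in radians.
#' @examples
#' heading(c(0, 0), c(0, -1)) # -pi/2
#' @export
heading <- function(a, b) {
  if (a[1] == b[1] && a[2] == b[2])
    stopf("heading is undefined for coincident points")
  atan2(b[2] - a[2], b[1] - a[1])
}

#' Relative turning angle at the middle of a triple of fixes
#'
#' Counter-clockwise-positive angle between the outgoing and incoming step
#' directions, in `(-pi, pi]`; 0 means straight ahead, `pi` a turn back.
#'
#' @param prev,cur,nxt points as length-2 numeric vectors.
#' @return Turning angle in radians.
#' @export
turning_angle <- function(prev, cur, nxt) {
  wrap_angle(heading(cur, nxt) - heading(prev, cur))
}

#' Resample a trajectory at a constant time step
#'
#' Piecewise-linear interpolation: between two fixes the animal is assumed
#' to travel in a straight line at constant speed. Original fixes are
#' preserved as samples whenever `dt` divides their elapsed time, and the
#' final fix is always appended so total duration and path length are
#' conserved.
#'
#' @param traj a [bcr_trajectory()].
#' @param dt resampling interval in minutes (> 0).
#' @return A new `bcr_trajectory` with constant `dt` (plus a possibly
#'   shorter final step).
#' @export
interpolate_path <- function(traj, dt) {
  if (dt <= 0) stopf("dt must be positive")
  tt <- cumsum(traj$dt)
  total <- tt[length(tt)]
  if (total == 0) {
    return(bcr_trajectory(traj$x, traj$y, traj$dt, id = traj$id))
  }
  if (dt > total)
    warnf("dt (%.3g) exceeds the total duration (%.3g); only endpoints kept",
          dt, total)
  tn <- seq(0, total, by = dt)
  if (tn[length(tn)] < total) tn <- c(tn, total)
  # zero-duration steps make time non-unique; keep last position at a time
  keep <- !duplicated(tt, fromLast = TRUE)
  xi <- stats::approx(tt[keep], traj$x[keep], xout = tn)$y
  yi <- stats::approx(tt[keep], traj$y[keep], xout = tn)$y
  bcr_trajectory(xi, yi, c(0, diff(tn)), id = traj$id)
}

#' Mean sampling time of a trajectory
#'
#' Average time between fixes. By convention the elapsed-time vector starts
#' at 0 for the first fix; the default averages the `n - 1` real intervals,
#' `include_first = TRUE` divides by `n` (the literal mean including the
#' leading 0).
#'
#' @param traj a [bcr_trajectory()].
#' @param include_first include the leading zero duration in the mean.
#' @return Mean interval in minutes.
#' @export
mean_sampling_time <- function(traj, include_first = FALSE) {
  n <- n_fixes(traj)
  if (n < 2) stopf("mean sampling time needs at least two fixes")
  if (include_first) mean(traj$dt) else mean(traj$dt[-1])
}

#' Apply a rigid motion (rotation then translation) to a trajectory
#'
#' Useful for invariance checks: the BCR estimator and all five statistics
#' are invariant under rigid motions of the inputs.
#'
#' @param traj a [bcr_trajectory()].
#' @param angle rotation angle in radians.
#' @param shift length-2 translation in metres.
#' @return The transformed `bcr_trajectory`.
#' @export
rigid_transform <- function(traj, angle = 0, shift = c(0, 0)) {
  ca <- cos(angle)
  sa <- sin(angle)
  bcr_trajectory(ca * traj$x - sa * traj$y + shift[1],
                 sa * traj$x + ca * traj$y + shift[2],
                 traj$dt, id = traj$id)
}
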