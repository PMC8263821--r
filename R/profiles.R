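#' Statistic profiles
#'
#' A named numeric summary of a trajectory produced by one of the five
#' evaluation statistics. Two profiles are comparable (see
#' [compare_profiles()]) iff they share the same `name` and labels.
#'
#' @param name statistic identifier.
#' @param values ordered numeric vector (finite, non-negative).
#' @param labels character labels, one per value.
#' @param meta optional list of settings recorded for provenance.
#' @return An object of class `bcr_profile`.
#' @export
bcr_profile <- function(name, values, labels, meta = list()) {
  values <- as.numeric(values)
  if (length(labels) != length(values)) stopf("one label per value required")
  if (anyNA(values) || any(!is.finite(values)) || any(values < 0))
    stopf("profile values must be finite and non-negative")
  structure(list(name = name, values = values, labels = as.character(labels),
                 meta = meta), class = "bcr_profile")
}

#' @export
print.bcr_profile <- function(x, ...) {
  cat(sprintf("<bcr_profile '%s': %d values, sum %.4g>\n",
              x$name, length(x$values), sum(x$values)))
  invisible(x)
}

#' @export
as.data.frame.bcr_profile <- function(x, ...) {
  data.frame(label = x$labels, value = x$values)
}

#' Distribution of relative turning angles
#'
#' Histogram (relative frequencies) of relative turning angles over all
#' triples of consecutive fixes whose incoming and outgoing displacements
#' both exceed `d_min`; immobile legs have no defined direction and are
#' excluded. Bins cover `(-pi, pi]`.
#'
#' @param traj a [bcr_trajectory()].
#' @param d_min immobility cutoff in metres.
#' @param n_bins number of angular bins.
#' @return A [bcr_profile()] named `"turning_angles"`.
#' @export
turning_angle_profile <- function(traj, d_min = 10, n_bins = 36) {
  len <- step_lengths(traj)
  n <- n_fixes(traj)
  if (n < 3) stopf("need at least 3 fixes")
  i <- 2:(n - 1)
  ok <- len[i - 1] > d_min & len[i] > d_min
  phi <- turning_angles(traj)[ok]
  if (length(phi) == 0) stopf("no eligible turning-angle triples (all legs <= d_min)")
  breaks <- seq(-pi, pi, length.out = n_bins + 1)
  # phi lies in (-pi, pi]; left-open right-closed bins match that range
  idx <- pmin(pmax(ceiling((phi + pi) / (2 * pi / n_bins)), 1L), n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bcr_profile("turning_angles", cnt / sum(cnt), sprintf("%.4f", centers),
              meta = list(d_min = d_min, n_bins = n_bins, n_angles = length(phi)))
}

# Plug-in bandwidth for one coordinate (Sheather-Jones direct plug-in, with
# fallbacks for small or discrete samples).
plugin_bandwidth <- function(v) {
  bw <- tryCatch(stats::bw.SJ(v, method = "dpi"),
                 error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0)
    bw <- tryCatch(stats::bw.nrd0(v), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(v), 1e-6)
  bw
}

# Bivariate Gaussian product-kernel density on a regular grid, chunked over
# points to bound memory. Returns list(gx, gy, z) with z[i, j] the density
# at (gx[i], gy[j]).
kde2d_grid <- function(x, y, hx, hy, gx, gy, chunk = 20000L) {
  n <- length(x)
  z <- matrix(0, length(gx), length(gy))
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    kx <- stats::dnorm(outer(gx, x[s:e], "-") / hx)      # |gx| x m
    ky <- stats::dnorm(outer(y[s:e], gy, "-") / hy)      # m x |gy|
    z <- z + kx %*% ky
  }
  z / (n * hx * hy)
}

#' Home-range isopleth areas from a kernel utilisation distribution
#'
#' Bivariate Gaussian kernel density estimate with a diagonal plug-in
#' bandwidth, evaluated on a `grid_size` x `grid_size` grid over the fixes
#' (padded by three bandwidths). For each percentage level the area of the
#' smallest highest-density region containing that share of the estimated
#' mass is reported in square metres.
#'
#' @param traj a [bcr_trajectory()] (or anything [as_trajectory()] accepts).
#' @param grid_size nodes per axis.
#' @param levels percentages of the utilisation distribution.
#' @param bandwidth optional length-2 override of the diagonal bandwidth
#'   (metres).
#' @return A [bcr_profile()] named `"home_range"`, one area per level.
#' @export
home_range_profile <- function(traj, grid_size = 210,
                               levels = c(100, 99, 95, 90, 80, 70, 60, 50,
                                          40, 30, 20, 10),
                               bandwidth = NULL) {
  traj <- as_trajectory(traj)
  x <- traj$x
  y <- traj$y
  if (diff(range(x)) == 0 && diff(range(y)) == 0)
    stopf("degenerate trajectory: all fixes identical")
  if (is.null(bandwidth)) {
    bandwidth <- c(plugin_bandwidth(x), plugin_bandwidth(y))
  } else if (any(bandwidth <= 0)) stopf("bandwidth must be positive")
  hx <- bandwidth[1]
  hy <- bandwidth[2]
  gx <- seq(min(x) - 3 * hx, max(x) + 3 * hx, length.out = grid_size)
  gy <- seq(min(y) - 3 * hy, max(y) + 3 * hy, length.out = grid_size)
  z <- kde2d_grid(x, y, hx, hy, gx, gy)
  cell <- (gx[2] - gx[1]) * (gy[2] - gy[1])
  mass <- sort(as.vector(z), decreasing = TRUE)
  mass <- mass / sum(mass)
  cum <- cumsum(mass)
  areas <- vapply(levels, function(q) {
    k <- which(cum >= q / 100 - 1e-12)[1]
    if (is.na(k)) k <- length(cum)
    k * cell
  }, numeric(1))
  bcr_profile("home_range", areas, sprintf("%g%%", levels),
              meta = list(grid_size = grid_size, bandwidth = bandwidth))
}

#' Area of the path dilated by disks of increasing radius
#'
#' The trajectory's polyline is rasterised into a binary window padded
#' beyond the largest radius (so the dilated set never touches the border),
#' and for each radius the area covered by the Minkowski sum of the path
#' with a disk of that radius is measured via an exact Euclidean distance
#' transform.
#'
#' @param traj a [bcr_trajectory()].
#' @param radii disk radii in metres (default 1-100).
#' @param resolution raster cell size in metres (1 m maps disk sizes 1-100
#'   to 1-100 pixels).
#' @param max_cells guard against accidental huge rasters.
#' @return A [bcr_profile()] named `"dilation"`, one area (m^2) per radius.
#' @export
dilation_profile <- function(traj, radii = 1:100, resolution = 1,
                             max_cells = 6e7) {
  traj <- as_trajectory(traj)
  if (n_fixes(traj) < 1) stopf("empty trajectory")
  pad <- max(radii) + 2 * resolution
  x0 <- min(traj$x) - pad
  y0 <- min(traj$y) - pad
  nc <- ceiling((diff(range(traj$x)) + 2 * pad) / resolution) + 1
  nr <- ceiling((diff(range(traj$y)) + 2 * pad) / resolution) + 1
  if (as.double(nr) * nc > max_cells)
    stopf("dilation raster would need %d cells; increase `resolution`",
          as.double(nr) * nc)
  mask <- cpp_rasterize_path(traj$x, traj$y, nr, nc, x0, y0, resolution)
  d <- cpp_edt(mask) * resolution
  areas <- vapply(radii, function(r) sum(d <= r) * resolution^2, numeric(1))
  bcr_profile("dilation", areas, sprintf("r%g", radii),
              meta = list(resolution = resolution))
}

#' Still (point) transect census
#'
#' Places `n_transects` fixed observers and counts, for each, the number of
#' times the animal's path enters its line-of-sight disk (crossings of the
#' interpolated path, not samples; starting inside counts one sighting).
#' Counts are sorted in decreasing order, breaking the spatial dependence,
#' and returned as the profile values.
#'
#' Observer placement is not part of the model: by default they are drawn
#' uniformly at random in the track's bounding box under `placement_seed`,
#' and any fixed layout can be supplied via `transects`.
#'
#' @param traj a [bcr_trajectory()].
#' @param sight line-of-sight radius in metres.
#' @param n_transects number of observers.
#' @param placement_seed seed for the uniform placement.
#' @param transects optional two-column matrix of observer coordinates
#'   overriding random placement.
#' @return A [bcr_profile()] named `"still_transects"` (sorted counts).
#' @export
still_transect_profile <- function(traj, sight = 200, n_transects = 100,
                                   placement_seed = 1, transects = NULL) {
  traj <- as_trajectory(traj)
  if (is.null(transects)) {
    transects <- with_seed(placement_seed, {
      cbind(stats::runif(n_transects, min(traj$x), max(traj$x)),
            stats::runif(n_transects, min(traj$y), max(traj$y)))
    })
  } else {
    transects <- as.matrix(transects)
    n_transects <- nrow(transects)
  }
  cnt <- cpp_crossing_counts(traj$x, traj$y, transects[, 1], transects[, 2],
                             sight)
  cnt <- sort(cnt, decreasing = TRUE)
  bcr_profile("still_transects", cnt, sprintf("rank%d", seq_along(cnt)),
              meta = list(sight = sight, n_transects = n_transects))
}

#' Mobile transect census
#'
#' The animal moves along its linearly interpolated path at its recorded
#' speeds while mobile observers survey the area on a shared discrete
#' clock. From each of the two anchor points (the first fix and the den)
#' eight linear transects depart in the 8 cardinal directions at constant
#' speed, with a fresh set of 16 spawned every `respawn_ticks` ticks, and
#' one rotational transect orbits each anchor clockwise on a 500 m radius.
#' A count is an entry of the animal into a transect's sight disk at the
#' clock resolution. Totals are aggregated over all transects of a type for
#' every (sight, speed) combination.
#'
#' @param traj a [bcr_trajectory()] with positive total duration.
#' @param sights line-of-sight radii in metres.
#' @param speed_multipliers transect speeds as multiples of the animal's
#'   average speed `s = path length / total time`.
#' @param respawn_ticks clock ticks between linear-transect respawns.
#' @param rotation_radius orbit radius of the rotational transects (m).
#' @param tick clock resolution in minutes; defaults to a tenth of the mean
#'   sampling time.
#' @param X_F den anchor; defaults to the isobarycentre.
#' @return A [bcr_profile()] named `"mobile_transects"` with one total per
#'   (type, sight, speed), labelled `<type>_s<sight>_v<multiplier>`.
#' @export
mobile_transect_profile <- function(traj,
                                    sights = c(50, 100, 200, 400, 500, 1000),
                                    speed_multipliers = c(0.25, 0.5, 1, 2),
                                    respawn_ticks = 10000,
                                    rotation_radius = 500,
                                    tick = NULL, X_F = NULL) {
  traj <- as_trajectory(traj)
  total <- sum(traj$dt)
  if (total <= 0) stopf("mobile transects need a trajectory with positive duration")
  if (is.null(tick)) tick <- mean_sampling_time(traj) / 10
  if (is.null(X_F)) X_F <- estimate_attractor(traj)
  s_bar <- path_length(traj) / total               # m / min
  tt <- cumsum(traj$dt)
  keep <- !duplicated(tt, fromLast = TRUE)
  ticks <- seq(0, total, by = tick)
  animal <- cbind(stats::approx(tt[keep], traj$x[keep], xout = ticks)$y,
                  stats::approx(tt[keep], traj$y[keep], xout = ticks)$y)
  vals <- numeric(0)
  labs <- character(0)
  for (m in speed_multipliers) {
    v <- m * s_bar * tick                          # metres per tick
    cnt <- cpp_mobile_transect_counts(animal, traj$x[1], traj$y[1],
                                      X_F[1], X_F[2], v,
                                      as.integer(respawn_ticks),
                                      rotation_radius, sights)
    for (type in 1:2) {
      vals <- c(vals, cnt[, type])
      labs <- c(labs, sprintf("%s_s%g_v%g",
                              c("linear", "rotational")[type], sights, m))
    }
  }
  bcr_profile("mobile_transects", vals, labs,
              meta = list(tick = tick, s_bar = s_bar,
                          respawn_ticks = respawn_ticks,
                          rotation_radius = rotation_radius))
}

#' Compare a reference profile against simulated ones
#'
#' Two reliability errors: `e1` is the L1 norm, the sum over simulations of
#' the summed absolute component differences from the reference; `e2` is
#' the mean relative error, the average over simulations of the mean
#' component-wise ratio simulated/reference (components with a zero
#' reference are skipped with a warning). Identical profiles give
#' `e1 = 0`, `e2 = 1`.
#'
#' @param reference a [bcr_profile()].
#' @param simulated a `bcr_profile` or list of them, same name and labels.
#' @return A list with `e1`, `e2`, `n_sim` and `name`.
#' @export
compare_profiles <- function(reference, simulated) {
  if (inherits(simulated, "bcr_profile")) simulated <- list(simulated)
  for (sim in simulated) {
    if (!identical(sim$name, reference$name) ||
        !identical(sim$labels, reference$labels))
      stopf("profiles are not comparable (different statistic or labels)")
  }
  ref <- reference$values
  pos <- ref > 0
  if (!all(pos))
    warnf("%d zero-reference component(s) skipped in e2", sum(!pos))
  if (!any(pos)) stopf("reference profile is all zero; e2 undefined")
  e1 <- sum(vapply(simulated, function(s) sum(abs(ref - s$values)), numeric(1)))
  e2 <- mean(vapply(simulated, function(s) mean(s$values[pos] / ref[pos]),
                    numeric(1)))
  list(e1 = e1, e2 = e2, n_sim = length(simulated), name = reference$name)
}

# Compute one named statistic profile with the package defaults; used by
# the experiment runners and the CLI.
compute_profile <- function(traj, which, d_min = 10, placement_seed = 1,
                            config = list()) {
  cfg <- utils::modifyList(bcr_config(), config)
  switch(which,
    turning_angles = turning_angle_profile(traj, d_min = d_min,
                                           n_bins = cfg$n_bins),
    home_range = home_range_profile(traj, grid_size = cfg$grid_size,
                                    levels = cfg$levels),
    dilation = dilation_profile(traj, radii = cfg$radii,
                                resolution = cfg$dilation_resolution),
    still_transects = still_transect_profile(traj, sight = cfg$sight,
                                             n_transects = cfg$n_transects,
                                             placement_seed = placement_seed),
    mobile_transects = mobile_transect_profile(
      traj, sights = cfg$sights, speed_multipliers = cfg$speed_multipliers,
      respawn_ticks = cfg$respawn_ticks, rotation_radius = cfg$rotation_radius),
    stopf("unknown statistic '%s'", which))
}
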