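#' Detect spatial voids with an alpha shape
#'
#' Computes the alpha shape of a point set at a fixed alpha radius and
#' extracts its interior holes ("voids"). The shape is realised as the
#' morphological closing of the point set with a disk of the alpha radius
#' on a fine raster: points are dilated by the radius (union of disks) and
#' the result eroded by the same radius, which reproduces the alpha-shape
#' boundary at raster resolution while preserving every hole a disk of
#' that radius cannot enter. Holes are 4-connected background components
#' not touching the window border; those at least `min_area` are reported.
#'
#' A void is flagged `central` when its centroid lies within `core_radius`
#' of the isobarycentre of the points (default: the median distance of the
#' points from that centre, i.e. the densely sampled core of the range).
#' Voids outside the core are usually artefacts of the low fix density
#' toward the range edge, where sampling gaps of arbitrary size arise from
#' rare excursions rather than from avoided terrain.
#'
#' @param points a two-column matrix/data.frame of planar coordinates, or a
#'   [bcr_trajectory()] (its fixes are used; the interpolated path is not).
#' @param alpha_radius alpha radius in metres.
#' @param min_area minimum void area to report, m^2.
#' @param resolution raster cell size in metres; by default chosen so the
#'   longer window side has about 1200 cells but never coarser than needed
#'   to resolve the alpha disk (and at least 2 m).
#' @param core_radius centrality radius in metres (default: median distance
#'   of the points from their isobarycentre).
#' @param polygons trace hole boundary polygons (disable in Monte-Carlo
#'   loops where only areas matter).
#' @return An object of class `bcr_voids`: a `voids` data.frame (`id`,
#'   `area`, `x`, `y`, `central`), a list of boundary `polygons`, the outer
#'   `shape_area`, and the settings used.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 400)
#' ring <- cbind(300 * cos(th), 300 * sin(th)) + matrix(rnorm(800, 0, 20), ncol = 2)
#' alpha_shape_voids(ring, alpha_radius = 60, min_area = 100)
#' @export
alpha_shape_voids <- function(points, alpha_radius = 60, min_area = 100,
                              resolution = NULL, core_radius = NULL,
                              polygons = TRUE) {
  if (inherits(points, "bcr_trajectory")) points <- cbind(points$x, points$y)
  points <- as.matrix(points)
  if (nrow(points) < 4) stopf("need at least 4 points")
  x <- points[, 1]
  y <- points[, 2]
  span <- max(diff(range(x)), diff(range(y)))
  if (span == 0) stopf("degenerate point set")
  ctr <- c(mean(x), mean(y))
  if (is.null(core_radius))
    core_radius <- stats::median(sqrt((x - ctr[1])^2 + (y - ctr[2])^2))
  if (is.null(resolution))
    resolution <- max(2, (span + 2 * alpha_radius) / 1200)
  res <- resolution
  pad <- alpha_radius + 3 * res
  x0 <- min(x) - pad
  y0 <- min(y) - pad
  nc <- ceiling((diff(range(x)) + 2 * pad) / res) + 1
  nr <- ceiling((diff(range(y)) + 2 * pad) / res) + 1

  pts <- cpp_rasterize_points(x, y, nr, nc, x0, y0, res)
  dil <- cpp_edt(pts) * res <= alpha_radius          # dilation by alpha
  # erosion of the dilation, with a one-cell tolerance; closing is
  # extensive, so the input cells are forced back in (a thin strand of
  # fixes must split a void exactly as the triangulated alpha shape would)
  closed <- (cpp_edt(!dil) * res > alpha_radius - res / 2) | pts
  shape_area <- sum(closed) * res^2

  bg <- cpp_label_components(!closed)
  border <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  border <- border[border > 0]

  # vectorised per-hole area and centroid
  lab <- as.vector(bg)
  inside <- lab > 0 & !(lab %in% border)
  gx <- x0 + (seq_len(nc) - 1) * res
  gy <- y0 + (seq_len(nr) - 1) * res
  voids <- list()
  polys <- list()
  if (any(inside)) {
    idx <- which(inside)
    li <- lab[idx]
    rows <- (idx - 1) %% nr + 1
    cols <- (idx - 1) %/% nr + 1
    sizes <- tapply(rep(1, length(li)), li, sum)
    keep <- names(sizes)[sizes * res^2 >= min_area]
    if (length(keep)) {
      cx_all <- tapply(gx[cols], li, mean)
      cy_all <- tapply(gy[rows], li, mean)
      for (h in keep) {
        area <- sizes[[h]] * res^2
        cx <- cx_all[[h]]
        cy <- cy_all[[h]]
        central <- sqrt((cx - ctr[1])^2 + (cy - ctr[2])^2) <= core_radius
        voids[[length(voids) + 1]] <-
          data.frame(area = area, x = cx, y = cy, central = central)
        polys[[length(polys) + 1]] <-
          if (polygons) hole_polygon(bg == as.integer(h), gx, gy) else NULL
      }
    }
  }
  if (length(voids)) {
    voids <- do.call(rbind, voids)
    ord <- order(-voids$area)
    voids <- voids[ord, , drop = FALSE]
    polys <- polys[ord]
    voids <- cbind(id = seq_len(nrow(voids)), voids)
    rownames(voids) <- NULL
  } else {
    voids <- data.frame(id = integer(0), area = numeric(0), x = numeric(0),
                        y = numeric(0), central = logical(0))
  }
  structure(list(voids = voids, polygons = polys, shape_area = shape_area,
                 alpha_radius = alpha_radius, min_area = min_area,
                 resolution = res, core_radius = core_radius, center = ctr),
            class = "bcr_voids")
}

# Boundary polygon of a hole mask via the 0.5-level contour of its
# indicator; falls back to the cell bounding box for one-cell holes.
hole_polygon <- function(mask, gx, gy) {
  z <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  cl <- grDevices::contourLines(x = gy, y = gx, z = z, levels = 0.5)
  if (length(cl) == 0) {
    cells <- which(mask, arr.ind = TRUE)
    return(cbind(x = range(gx[cells[, 2]])[c(1, 2, 2, 1)],
                 y = range(gy[cells[, 1]])[c(1, 1, 2, 2)]))
  }
  best <- cl[[which.max(vapply(cl, function(c) length(c$x), numeric(1)))]]
  cbind(x = best$y, y = best$x)  # contourLines x runs over rows (= gy)
}

#' @export
print.bcr_voids <- function(x, ...) {
  cat(sprintf("<bcr_voids: %d void(s) >= %g m^2 (%d central), shape %.4g m^2, alpha %g m>\n",
              nrow(x$voids), x$min_area, sum(x$voids$central),
              x$shape_area, x$alpha_radius))
  invisible(x)
}

#' Monte-Carlo null distribution of void sizes under the BCR
#'
#' Simulates `n_iter` BCR paths with the fitted parameters and, for each,
#' extracts the central voids of the fix set's alpha shape. The null
#' probability `p_empty(a)` is the fraction of simulated paths containing a
#' central void of area at least `a`.
#'
#' @param params a [bcr_params()] (typically from [as_bcr_params()]).
#' @param n_steps steps per simulated path (match the data size).
#' @param n_iter Monte-Carlo iterations.
#' @param area_grid area thresholds (m^2) for the reported curve.
#' @param seed integer seed.
#' @param alpha_radius,min_area,resolution passed to [alpha_shape_voids()].
#' @param central_only restrict the null to central voids (mirrors the
#'   empirical analysis).
#' @return An object of class `bcr_void_null`: `area`, `p_empty`, the raw
#'   per-iteration `max_areas`, and `n_iter`.
#' @export
void_null_distribution <- function(params, n_steps, n_iter = 200,
                                   area_grid = NULL, seed = NULL,
                                   alpha_radius = 60, min_area = 100,
                                   resolution = NULL, central_only = TRUE) {
  if (n_iter < 1) stopf("n_iter must be at least 1")
  max_areas <- vapply(seq_len(n_iter), function(i) {
    tr <- simulate_bcr(params, n_steps,
                       seed = if (is.null(seed)) NULL else child_seed(seed, i))
    rep_i <- alpha_shape_voids(tr, alpha_radius = alpha_radius,
                               min_area = min_area, resolution = resolution,
                               polygons = FALSE)
    v <- rep_i$voids
    if (central_only) v <- v[v$central, , drop = FALSE]
    if (nrow(v) == 0) 0 else max(v$area)
  }, numeric(1))
  if (is.null(area_grid))
    area_grid <- c(0, 100, 250, 500, 1000, 2500, 5000, 10000, 25000, 50000,
                   100000)
  p_empty <- vapply(area_grid, function(a) mean(max_areas >= a), numeric(1))
  structure(list(area = area_grid, p_empty = p_empty, max_areas = max_areas,
                 n_iter = n_iter, alpha_radius = alpha_radius,
                 min_area = min_area, central_only = central_only),
            class = "bcr_void_null")
}

#' @export
print.bcr_void_null <- function(x, ...) {
  cat(sprintf("<bcr_void_null: %d iterations, p_empty from %.2f (a=%g) to %.2f (a=%g)>\n",
              x$n_iter, x$p_empty[1], x$area[1],
              x$p_empty[length(x$p_empty)], x$area[length(x$area)]))
  invisible(x)
}

#' Flag voids unexplained by movement randomness
#'
#' A central void is anomalous when the null probability of seeing a void
#' at least as large, `p_empty(area)`, falls below `p_cut`: the hole is
#' then likely due to a real spatial feature (enclosure, water, building)
#' rather than to randomness of the walk.
#'
#' @param report a `bcr_voids` object from [alpha_shape_voids()].
#' @param null a `bcr_void_null` from [void_null_distribution()].
#' @param p_cut significance threshold on `p_empty`.
#' @return The `voids` data.frame of `report` restricted to central voids,
#'   with `p_empty` and `anomalous` columns added.
#' @export
flag_anomalous_voids <- function(report, null, p_cut = 0.05) {
  v <- report$voids[report$voids$central, , drop = FALSE]
  if (nrow(v) == 0) {
    return(cbind(v, p_empty = numeric(0), anomalous = logical(0)))
  }
  v$p_empty <- vapply(v$area, function(a) mean(null$max_areas >= a),
                      numeric(1))
  v$anomalous <- v$p_empty < p_cut
  rownames(v) <- NULL
  v
}
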