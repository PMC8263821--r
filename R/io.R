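#' Run configuration defaults
#'
#' All tunable settings in one flat list, initialised to the standard
#' analysis defaults: 10 m immobility cutoff, pi/8 angular half-width,
#' 210-node home-range grid, disk radii 1-100 m, 200 m still-transect
#' sight, mobile-transect sights \{50, 100, 200, 400, 500, 1000\} m with
#' speed multipliers \{1/4, 1/2, 1, 2\} and respawn every 10,000 ticks on a
#' 500 m rotation radius, 60 m alpha radius and 100 m^2 minimum void area.
#' Every entry can be overridden via `...` or a key=value config file
#' ([read_config()]).
#'
#' @param ... named overrides.
#' @return A named list.
#' @export
bcr_config <- function(...) {
  cfg <- list(
    d_min = 10, half_width = pi / 8, T_bar = 10,
    n_bins = 36,
    grid_size = 210,
    levels = c(100, 99, 95, 90, 80, 70, 60, 50, 40, 30, 20, 10),
    radii = 1:100, dilation_resolution = 1,
    sight = 200, n_transects = 100,
    sights = c(50, 100, 200, 400, 500, 1000),
    speed_multipliers = c(0.25, 0.5, 1, 2),
    respawn_ticks = 10000, rotation_radius = 500,
    alpha_radius = 60, min_void_area = 100, p_cut = 0.05,
    n_sim = 1000, seed = 1
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, over)
  }
  cfg
}

#' Read and write flat key=value configuration files
#'
#' One `key = value` pair per line; `#` starts a comment; vector values are
#' comma-separated. Unknown keys are rejected so typos surface early.
#'
#' @param path file path.
#' @param config a config list (from [bcr_config()]) for writing.
#' @return `read_config()` returns a full config list with the file's
#'   overrides applied.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stopf("malformed config line: '%s'", ln)
    key <- trimws(kv[1])
    val <- as.numeric(strsplit(trimws(kv[2]), ",", fixed = TRUE)[[1]])
    if (anyNA(val)) stopf("non-numeric config value in line: '%s'", ln)
    over[[key]] <- val
  }
  do.call(bcr_config, over)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, paste(format(config[[k]], digits = 15), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

# Local equirectangular projection about the track centroid: exact inverse,
# adequate at home-range scales (a few km). Earth mean radius, metres.
.earth_radius <- 6371008.8

lonlat_to_metric <- function(lon, lat, origin = NULL) {
  if (is.null(origin)) origin <- c(mean(lon), mean(lat))
  rad <- pi / 180
  x <- (lon - origin[1]) * rad * .earth_radius * cos(origin[2] * rad)
  y <- (lat - origin[2]) * rad * .earth_radius
  list(x = x, y = y, origin = origin)
}

metric_to_lonlat <- function(x, y, origin) {
  rad <- pi / 180
  list(lon = origin[1] + x / (.earth_radius * cos(origin[2] * rad)) / rad,
       lat = origin[2] + y / .earth_radius / rad)
}

# ISO-8601-ish timestamp parsing that yields NA (not an error) for
# malformed entries, so bad rows can be reported with their line numbers.
parse_timestamps <- function(x) {
  out <- rep(as.POSIXct(NA), length(x))
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], fmt, tz = "UTC"), tz = "UTC")
  }
  out
}

#' Read a GPS track file
#'
#' Expects a CSV with header `animal_id, timestamp, x, y` (planar metres)
#' or `animal_id, timestamp, lon, lat` with `projection = "lonlat"`, in
#' which case coordinates are projected onto a local planar frame about the
#' track centroid (stored in the result for exact back-conversion).
#' Timestamps (ISO-8601) must be strictly increasing per animal; one animal
#' is analysed per run.
#'
#' @param path CSV file path.
#' @param projection `"metric"` (default) or `"lonlat"`.
#' @param animal id to select when the file holds several animals.
#' @return A [bcr_trajectory()] with durations in minutes; for lon/lat
#'   input the projection origin is attached as attribute
#'   `"projection_origin"`.
#' @export
read_track <- function(path, projection = c("metric", "lonlat"),
                       animal = NULL) {
  projection <- match.arg(projection)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coords <- if (projection == "metric") c("x", "y") else c("lon", "lat")
  need <- c("animal_id", "timestamp", coords)
  if (!all(need %in% names(df)))
    stopf("track file must have columns: %s", paste(need, collapse = ", "))
  ids <- unique(df$animal_id)
  if (length(ids) > 1) {
    if (is.null(animal))
      stopf("file holds %d animals (%s); select one with `animal`",
            length(ids), paste(utils::head(ids, 5), collapse = ", "))
    df <- df[df$animal_id == animal, , drop = FALSE]
    if (nrow(df) == 0) stopf("no rows for animal '%s'", animal)
  }
  ts <- parse_timestamps(df$timestamp)
  bad <- which(is.na(ts) | is.na(df[[coords[1]]]) | is.na(df[[coords[2]]]))
  if (length(bad))
    stopf("malformed row(s) at line(s) %s of %s",
          paste(utils::head(bad + 1, 10), collapse = ", "), path)
  if (any(diff(as.numeric(ts)) <= 0)) {
    row <- which(diff(as.numeric(ts)) <= 0)[1] + 1
    stopf("timestamps not strictly increasing at data row %d (file line %d)",
          row, row + 1)
  }
  dtm <- c(0, diff(as.numeric(ts)) / 60)
  if (projection == "lonlat") {
    pr <- lonlat_to_metric(df[[coords[1]]], df[[coords[2]]])
    tr <- bcr_trajectory(pr$x, pr$y, dtm, id = df$animal_id[1])
    attr(tr, "projection_origin") <- pr$origin
    tr
  } else {
    bcr_trajectory(df[[coords[1]]], df[[coords[2]]], dtm,
                   id = df$animal_id[1])
  }
}

#' Write a trajectory as a track CSV
#'
#' @param traj a [bcr_trajectory()].
#' @param path output CSV path.
#' @param start_time POSIXct timestamp of the first fix.
#' @param animal id written to the `animal_id` column (the trajectory's own
#'   id when present).
#' @return The path, invisibly.
#' @export
write_track <- function(traj, path,
                        start_time = as.POSIXct("2010-01-01 00:00:00",
                                                tz = "UTC"),
                        animal = NULL) {
  if (is.null(animal)) animal <- if (is.null(traj$id)) "sim" else traj$id
  ts <- start_time + cumsum(traj$dt) * 60
  df <- data.frame(animal_id = animal,
                   timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   x = traj$x, y = traj$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic GPS fixture track
#'
#' Emulates a deer-like GPS dataset: a BCR path simulated at a nominal
#' 10-minute interval with Gaussian timestamp jitter, an attractor, a large
#' immobile fraction, and optionally a planted exclusion polygon (proposed
#' steps landing inside are redrawn), which leaves an artificial void in
#' the fix set.
#'
#' @param params a [bcr_params()]; the default
#'   (`p_I = 0.1, p_s = 1.9, p_F = 1, mu = 3, sigma = 1`) reproduces the
#'   shape of a real female red-deer dataset: a stationary home range about
#'   2.5-3.5 km across, log-normal steps around 30-45 m, and roughly 17%
#'   exactly-immobile fixes. (The published weight estimates confine much
#'   more weakly than the animals they were fitted to; a stationary
#'   attractor at data-like density needs the stronger bias.)
#' @param n number of fixes.
#' @param exclusion optional polygon (two-column matrix, metres).
#' @param jitter_sd standard deviation of the timestamp jitter, minutes.
#'   Jitter violating strict monotonicity is redrawn.
#' @param seed integer seed.
#' @param path optional CSV path; when given the track is also written via
#'   [write_track()].
#' @param origin simulation origin.
#' @return The [bcr_trajectory()], invisibly when `path` is given.
#' @export
generate_fixture <- function(params = NULL, n = 25000, exclusion = NULL,
                             jitter_sd = 3, seed = NULL, path = NULL,
                             origin = NULL) {
  if (is.null(params))
    params <- bcr_params(p_I = 0.1, p_s = 1.9, p_F = 1, mu = 3, sigma = 1)
  if (is.null(origin)) origin <- params$X_F
  tr <- with_seed(seed, {
    tr0 <- simulate_bcr(params, n - 1, origin = origin,
                        exclusion = exclusion)
    tt <- seq_len(n - 1) * params$T_bar +
      stats::rnorm(n - 1, 0, jitter_sd)
    tt <- c(0, tt)
    for (guard in 1:100) {
      bad <- which(diff(tt) <= 0)
      if (!length(bad)) break
      tt[bad + 1] <- (bad) * params$T_bar + stats::rnorm(length(bad), 0, jitter_sd)
    }
    if (any(diff(tt) <= 0)) { # give up jittering the stragglers
      tt <- cummax(tt + seq_along(tt) * 1e-9)
    }
    bcr_trajectory(tr0$x, tr0$y, c(0, diff(tt)), id = "fixture")
  })
  if (!is.null(path)) {
    write_track(tr, path)
    return(invisible(tr))
  }
  tr
}

#' Serialise an estimate as JSON
#'
#' @param est a `bcr_estimate` from [estimate_bcr()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_estimate_json <- function(est, path) {
  obj <- list(
    p_I = est$p_I, p_s = est$p_s, p_F = est$p_F,
    mu = est$mu, sigma = est$sigma, chi = est$chi,
    X_F = est$X_F, d_min = est$d_min,
    negative = if (length(est$negative)) est$negative else character(0),
    counts = est$counts[c("n_states", "n_H", "n_HIF", "n_HIs",
                          "c_I", "c_s", "c_F")],
    proportions = est$proportions[c("x1", "x2", "x3")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a statistic profile as CSV
#'
#' @param profile a [bcr_profile()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Export voids as GeoJSON
#'
#' Writes the void polygons of a `bcr_voids` report as a GeoJSON
#' FeatureCollection with `area`, `central` and (when a null distribution
#' is supplied) `p_empty` properties. Coordinates stay in the planar metric
#' frame of the analysis.
#'
#' @param report a `bcr_voids` from [alpha_shape_voids()].
#' @param path output path.
#' @param null optional `bcr_void_null` for `p_empty` attributes.
#' @return The path, invisibly.
#' @export
write_voids_geojson <- function(report, path, null = NULL) {
  feats <- lapply(seq_len(nrow(report$voids)), function(i) {
    v <- report$voids[i, ]
    poly <- report$polygons[[i]]
    ring <- lapply(seq_len(nrow(poly)), function(j) c(poly[j, 1], poly[j, 2]))
    if (!identical(ring[[1]], ring[[length(ring)]]))
      ring <- c(ring, ring[1])
    props <- list(id = v$id, area = v$area, central = v$central)
    if (!is.null(null)) props$p_empty <- mean(null$max_areas >= v$area)
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a void-null curve as CSV
#'
#' @param null a `bcr_void_null`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_void_null_csv <- function(null, path) {
  utils::write.csv(data.frame(area = null$area, p_empty = null$p_empty),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
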