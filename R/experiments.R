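#' Fluctuation study: variance of the statistics vs. path length
#'
#' Assesses how deterministic each statistic is: for each number of steps
#' `n_s`, `replicates` BCR paths are simulated and the per-component
#' variance of each statistic across replicates is averaged into a single
#' variance figure. Statistics whose variance shrinks (or at least does not
#' grow) with `n_s` are reliable references for model evaluation.
#'
#' @param params a [bcr_params()].
#' @param n_s_grid path lengths to test (steps).
#' @param replicates simulated paths per grid value.
#' @param statistics which profiles to evaluate.
#' @param d_min cutoff used by the turning-angle filter.
#' @param seed integer seed driving all simulations.
#' @param normalize scale count-valued statistics (the transect censuses)
#'   to sightings per step before taking variances. Raw census counts grow
#'   linearly with the recording length, so their across-replicate variance
#'   necessarily grows with `n_s`; the per-step rate is the scale on which
#'   "the statistic is deterministic" is a meaningful question.
#'   Distribution-valued statistics (turning angles, home range, dilation)
#'   are left untouched.
#' @return A data.frame with columns `n_s`, `statistic`, `variance`.
#' @export
fluctuation_study <- function(params,
                              n_s_grid = seq(1e4, 4e5, by = 1e4),
                              replicates = 100,
                              statistics = c("turning_angles",
                                             "still_transects"),
                              d_min = 10, seed = NULL, normalize = TRUE) {
  if (replicates < 2) stopf("need at least 2 replicates for a variance")
  rows <- list()
  # One fixed observer layout for the whole study (the census layout does
  # not move between realisations): drawn once in the bounding box of a
  # pilot path at the largest n_s.
  transects <- NULL
  if ("still_transects" %in% statistics) {
    cfg <- bcr_config()
    pilot <- simulate_bcr(params, max(n_s_grid),
                          seed = if (is.null(seed)) NULL else child_seed(seed, 0))
    transects <- with_seed(if (is.null(seed)) NULL else child_seed(seed, 1), {
      cbind(stats::runif(cfg$n_transects, min(pilot$x), max(pilot$x)),
            stats::runif(cfg$n_transects, min(pilot$y), max(pilot$y)))
    })
  }
  for (n_s in n_s_grid) {
    profs <- lapply(seq_len(replicates), function(r) {
      tr <- simulate_bcr(params, n_s,
                         seed = if (is.null(seed)) NULL
                                else child_seed(seed, n_s + r))
      lapply(statistics, function(st) {
        if (st == "still_transects")
          still_transect_profile(tr, sight = bcr_config()$sight,
                                 transects = transects)
        else compute_profile(tr, st, d_min = d_min, placement_seed = r)
      })
    })
    for (j in seq_along(statistics)) {
      vals <- do.call(rbind, lapply(profs, function(p) p[[j]]$values))
      if (normalize &&
          statistics[j] %in% c("still_transects", "mobile_transects"))
        vals <- vals / n_s
      rows[[length(rows) + 1]] <-
        data.frame(n_s = n_s, statistic = statistics[j],
                   variance = mean(apply(vals, 2, stats::var)))
    }
  }
  do.call(rbind, rows)
}

#' Arbitrary parameter configurations for the sensitivity sweep
#'
#' Deterministic set of 151 weight configurations: a 5x5x5 local mesh of
#' offsets (-0.2 ... +0.2, clipped at 0) around the centre estimate, three
#' single-force configurations at the centre values, and 23 distant
#' configurations on a coarse grid reaching the bounds `p_I = 3`,
#' `p_s = 5`, `p_F = 3`.
#'
#' @param center a [bcr_params()] or list with `p_I`, `p_s`, `p_F` (mesh
#'   centre, typically the data-driven estimate).
#' @return A data.frame of `p_I`, `p_s`, `p_F` with a `kind` column
#'   (`mesh`, `single`, `distant`).
#' @export
sensitivity_configs <- function(center) {
  off <- c(-0.2, -0.1, 0, 0.1, 0.2)
  mesh <- expand.grid(p_I = pmax(0, center$p_I + off),
                      p_s = pmax(0, center$p_s + off),
                      p_F = pmax(0, center$p_F + off))
  mesh <- mesh[!duplicated(mesh), , drop = FALSE]
  mesh$kind <- "mesh"
  single <- data.frame(p_I = c(center$p_I, 0, 0),
                       p_s = c(0, center$p_s, 0),
                       p_F = c(0, 0, center$p_F),
                       kind = "single")
  distant <- expand.grid(p_I = c(0, 1.5, 3), p_s = c(0, 2.5, 5),
                         p_F = c(0, 1.5, 3))
  # drop the origin and the three near-axis points to land on 23 rows
  nz <- rowSums(distant > 0)
  distant <- distant[!(nz == 0 |
                       (nz == 1 & (distant$p_I == 1.5 | distant$p_s == 2.5 |
                                   distant$p_F == 1.5))), ]
  distant$kind <- "distant"
  out <- rbind(mesh, single, distant)
  rownames(out) <- NULL
  out$config_id <- seq_len(nrow(out))
  out
}

#' Sensitivity sweep over arbitrary parameter configurations
#'
#' Replays the evaluation framework with injected weights instead of
#' data-driven estimates: for each configuration, `n_sim` BCR paths are
#' simulated (step-length law, den and step count taken from the reference)
#' and each statistic is compared against the reference profile; the mean
#' and standard deviation of the per-simulation absolute error are
#' reported.
#'
#' @param reference a [bcr_trajectory()] serving as ground truth.
#' @param configs data.frame with columns `p_I`, `p_s`, `p_F` (see
#'   [sensitivity_configs()]).
#' @param n_sim simulations per configuration.
#' @param statistics which profiles to evaluate.
#' @param base_params a [bcr_params()] supplying `mu`, `sigma`, `X_F`,
#'   `d_min` and `T_bar`; defaults to the estimate from `reference`.
#' @param n_steps steps per simulated path; defaults to the reference size.
#' @param d_min cutoff for the turning-angle filter.
#' @param seed integer seed.
#' @return A long data.frame: `config_id`, `p_I`, `p_s`, `p_F`,
#'   `statistic`, `mean_abs_err`, `sd_abs_err`.
#' @export
sensitivity_sweep <- function(reference, configs, n_sim = 150,
                              statistics = c("turning_angles"),
                              base_params = NULL, n_steps = NULL,
                              d_min = 10, seed = NULL) {
  if (nrow(configs) < 1) stopf("configs must be non-empty")
  if (is.null(base_params)) {
    est <- suppressWarnings(estimate_bcr(reference, d_min = d_min))
    base_params <- bcr_params(p_I = max(0, est$p_I), p_s = max(0, est$p_s),
                              p_F = max(0, est$p_F), mu = est$mu,
                              sigma = est$sigma, X_F = est$X_F,
                              d_min = d_min)
  }
  if (is.null(n_steps)) n_steps <- n_fixes(reference) - 1
  ref_profiles <- lapply(statistics, function(st)
    compute_profile(reference, st, d_min = d_min, placement_seed = 1))
  rows <- list()
  for (ci in seq_len(nrow(configs))) {
    p <- bcr_params(p_I = configs$p_I[ci], p_s = configs$p_s[ci],
                    p_F = configs$p_F[ci], mu = base_params$mu,
                    sigma = base_params$sigma, X_F = base_params$X_F,
                    d_min = base_params$d_min, T_bar = base_params$T_bar)
    errs <- matrix(NA_real_, n_sim, length(statistics))
    for (k in seq_len(n_sim)) {
      tr <- simulate_bcr(p, n_steps,
                         seed = if (is.null(seed)) NULL
                                else child_seed(seed, ci * 1000 + k))
      for (j in seq_along(statistics)) {
        sim_prof <- compute_profile(tr, statistics[j], d_min = d_min,
                                    placement_seed = k)
        errs[k, j] <- sum(abs(ref_profiles[[j]]$values - sim_prof$values))
      }
    }
    for (j in seq_along(statistics)) {
      rows[[length(rows) + 1]] <- data.frame(
        config_id = if ("config_id" %in% names(configs)) configs$config_id[ci] else ci,
        p_I = configs$p_I[ci], p_s = configs$p_s[ci], p_F = configs$p_F[ci],
        statistic = statistics[j],
        mean_abs_err = mean(errs[, j]), sd_abs_err = stats::sd(errs[, j]))
    }
  }
  do.call(rbind, rows)
}
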