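#' Estimate the attractor of a trajectory
#'
#' The den is estimated as the isobarycentre (component-wise mean) of all
#' recorded locations.
#'
#' @param traj a [bcr_trajectory()].
#' @return Length-2 numeric point.
#' @export
estimate_attractor <- function(traj) {
  if (n_fixes(traj) < 1) stopf("empty trajectory")
  c(mean(traj$x), mean(traj$y))
}

#' Tally states and situations along a trajectory
#'
#' For every interior fix `i` the state of the pair `(X[i-1], X[i])` is
#' classified (`H`, `H_IF` or `H_Is`, see [classify_state()]). For states in
#' `H`, membership of the triple `(X[i-1], X[i], X[i+1])` in the three
#' situations is counted:
#' \describe{
#'   \item{I (inertia)}{relative turning angle within `half_width` of 0;}
#'   \item{s (immobility)}{outgoing displacement at most `d_min`;}
#'   \item{F (attraction)}{outgoing heading within `half_width` of the den
#'     direction.}
#' }
#' `I` and `F` are only evaluated on mobile outgoing steps
#' (`> d_min`), and a triple may count in both (the narrow cones can
#' overlap; the overlap is left unresolved by design). States in `H` whose
#' outgoing step is immobile stay in the denominator: they are legitimately
#' classifiable as situation `s`.
#'
#' @param traj a [bcr_trajectory()] with at least 3 fixes.
#' @param X_F the den; defaults to [estimate_attractor()].
#' @param d_min immobility cutoff in metres.
#' @param half_width angular half-width of a quadrant, radians.
#' @return An object of class `bcr_situations`: counts `n_H`, `n_HIF`,
#'   `n_HIs`, `c_I`, `c_s`, `c_F` plus the settings used.
#' @export
classify_situations <- function(traj, X_F = NULL, d_min = 10,
                                half_width = pi / 8) {
  n <- n_fixes(traj)
  if (n < 3) stopf("situation classification needs at least 3 fixes")
  if (is.null(X_F)) X_F <- estimate_attractor(traj)

  len <- step_lengths(traj)      # len[i] = d(X_i, X_{i+1}), i = 1..n-1
  hd <- step_headings(traj)      # heading of step i (NA if zero length)
  den_dir <- atan2(X_F[2] - traj$y, X_F[1] - traj$x)  # at each fix

  i <- 2:(n - 1)                 # interior indices
  inc <- len[i - 1]              # incoming displacement
  out <- len[i]                  # outgoing displacement

  is_His <- inc <= d_min
  to_den <- abs(angle_difference(hd[i - 1], den_dir[i])) <= half_width
  is_Hif <- !is_His & to_den
  is_H <- !is_His & !is_Hif

  phi <- wrap_angle(hd[i] - hd[i - 1])                 # relative turning
  out_to_den <- abs(angle_difference(hd[i], den_dir[i])) <= half_width
  mobile_out <- out > d_min

  c_s <- sum(is_H & out <= d_min)
  c_I <- sum(is_H & mobile_out & abs(phi) <= half_width, na.rm = TRUE)
  c_F <- sum(is_H & mobile_out & out_to_den, na.rm = TRUE)

  structure(list(n_states = length(i),
                 n_H = sum(is_H), n_HIF = sum(is_Hif), n_HIs = sum(is_His),
                 c_I = c_I, c_s = c_s, c_F = c_F,
                 d_min = d_min, half_width = half_width, X_F = X_F),
            class = "bcr_situations")
}

#' @export
print.bcr_situations <- function(x, ...) {
  cat(sprintf("<bcr_situations: %d states (H %d, H_IF %d, H_Is %d); I %d, s %d, F %d>\n",
              x$n_states, x$n_H, x$n_HIF, x$n_HIs, x$c_I, x$c_s, x$c_F))
  invisible(x)
}

#' Situation proportions
#'
#' Empirical proportions `x1 = #I/#H`, `x2 = #s/#H`, `x3 = #F/#H` over the
#' non-conflicting states, the quantities inverted by
#' [invert_parameters()].
#'
#' @param counts a `bcr_situations` object from [classify_situations()].
#' @return A list with `x1`, `x2`, `x3` and `n_H`.
#' @export
situation_proportions <- function(counts) {
  if (counts$n_H < 1) stopf("no non-conflicting states; cannot form proportions")
  list(x1 = counts$c_I / counts$n_H,
       x2 = counts$c_s / counts$n_H,
       x3 = counts$c_F / counts$n_H,
       n_H = counts$n_H)
}

#' Forward map from weights to situation proportions
#'
#' The model-implied proportions `x1 = (1 + p_I)/chi`, `x2 = p_s/chi`,
#' `x3 = (1 + p_F)/chi`. Exact algebraic inverse of
#' [invert_parameters()]; used for round-trip checks.
#'
#' @param params a [bcr_params()].
#' @return A list with `x1`, `x2`, `x3`.
#' @export
params_to_proportions <- function(params) {
  chi <- chi_value(params)
  list(x1 = (1 + params$p_I) / chi,
       x2 = params$p_s / chi,
       x3 = (1 + params$p_F) / chi)
}

#' Invert situation proportions into BCR weights
#'
#' Closed-form inversion: `chi = m / (1 - (x1 + x2 + x3))` with
#' `m = 8 - (number of active angular situations)`, then `p_I = x1*chi - 1`,
#' `p_s = x2*chi`, `p_F = x3*chi - 1`. With all three situations active
#' `m = 6` (the I and F cones each absorb one diffusion quadrant). Reduced
#' configurations (subsets of situations, as used in one-parameter
#' sensitivity runs) adjust `m` accordingly: immobility occupies no cone.
#'
#' Negative results are returned as-is with a `negative` flag -- they signal
#' a direction the animal avoids and must not be fed back into the
#' simulator.
#'
#' @param x1,x2,x3 situation proportions (pass `NULL` for situations not in
#'   `active`).
#' @param active character subset of `c("I", "s", "F")`.
#' @return A list with the active weights, `chi` and `negative` (character
#'   vector of flagged weights).
#' @export
invert_parameters <- function(x1 = NULL, x2 = NULL, x3 = NULL,
                              active = c("I", "s", "F")) {
  active <- match.arg(active, c("I", "s", "F"), several.ok = TRUE)
  xs <- c(I = if ("I" %in% active) x1, s = if ("s" %in% active) x2,
          F = if ("F" %in% active) x3)
  if (length(xs) != length(active))
    stopf("a proportion must be supplied for every active situation")
  total <- sum(xs)
  if (total >= 1)
    stopf("x1 + x2 + x3 = %.4f >= 1: proportions are not invertible; rethink the design", total)
  m <- 8 - sum(active %in% c("I", "F"))
  chi <- m / (1 - total)
  out <- list(p_I = NA_real_, p_s = NA_real_, p_F = NA_real_, chi = chi)
  if ("I" %in% active) out$p_I <- x1 * chi - 1
  if ("s" %in% active) out$p_s <- x2 * chi
  if ("F" %in% active) out$p_F <- x3 * chi - 1
  neg <- c("p_I", "p_s", "p_F")[!is.na(unlist(out[1:3])) & unlist(out[1:3]) < 0]
  out$negative <- neg
  if (length(neg))
    warnf("negative estimated weight(s): %s (flagged, not clipped)",
          paste(neg, collapse = ", "))
  out
}

#' Fit the log-normal step-length distribution
#'
#' Maximum-likelihood log-normal fit over mobile steps (displacement
#' strictly greater than `d_min`): `mu` is the mean and `sigma` the ML
#' standard deviation of the log displacements.
#'
#' @param traj a [bcr_trajectory()].
#' @param d_min immobility cutoff in metres.
#' @return A list with `mu`, `sigma` and `n_steps` used.
#' @export
fit_step_distribution <- function(traj, d_min = 10) {
  len <- step_lengths(traj)
  len <- len[len > d_min]
  if (length(len) < 2) stopf("need at least 2 mobile steps to fit the step distribution")
  lg <- log(len)
  mu <- mean(lg)
  sigma <- sqrt(mean((lg - mu)^2))
  list(mu = mu, sigma = sigma, n_steps = length(lg))
}

#' Estimate BCR parameters from a trajectory
#'
#' Full closed-form estimation pipeline: attractor as isobarycentre, state
#' and situation tallies, proportions, algebraic inversion into
#' `(p_I, p_s, p_F)`, and the log-normal step-length fit.
#'
#' @param traj a [bcr_trajectory()] with at least 3 fixes.
#' @param d_min immobility cutoff in metres. `d_min = 0` classifies only
#'   exact zero displacements as immobile, which removes the short-step
#'   inflation of `p_s` (log-normal steps shorter than a positive `d_min`
#'   are otherwise counted as rest).
#' @param half_width angular half-width of a quadrant, radians.
#' @param X_F optionally fix the den instead of estimating it.
#' @param active subset of situations to estimate (see
#'   [invert_parameters()]).
#' @return An object of class `bcr_estimate`: weights, `mu`, `sigma`,
#'   `X_F`, `chi`, the `counts` and `proportions`, and `negative` flags.
#' @examples
#' p <- bcr_params(p_I = 0.1, p_s = 1.5, p_F = 0.1)
#' tr <- simulate_bcr(p, 5000, seed = 1)
#' estimate_bcr(tr, d_min = 0)
#' @export
estimate_bcr <- function(traj, d_min = 10, half_width = pi / 8, X_F = NULL,
                         active = c("I", "s", "F")) {
  if (is.null(X_F)) X_F <- estimate_attractor(traj)
  counts <- classify_situations(traj, X_F = X_F, d_min = d_min,
                                half_width = half_width)
  prop <- situation_proportions(counts)
  inv <- invert_parameters(prop$x1, prop$x2, prop$x3, active = active)
  step_fit <- fit_step_distribution(traj, d_min = d_min)
  structure(list(p_I = inv$p_I, p_s = inv$p_s, p_F = inv$p_F,
                 mu = step_fit$mu, sigma = step_fit$sigma,
                 X_F = X_F, chi = inv$chi, negative = inv$negative,
                 counts = counts, proportions = prop,
                 d_min = d_min, half_width = half_width),
            class = "bcr_estimate")
}

#' @export
print.bcr_estimate <- function(x, ...) {
  cat(sprintf(
    "<bcr_estimate: p_I=%.3f p_s=%.3f p_F=%.3f (chi=%.2f), mu=%.3f sigma=%.3f, X_F=(%.1f, %.1f)%s>\n",
    x$p_I, x$p_s, x$p_F, x$chi, x$mu, x$sigma, x$X_F[1], x$X_F[2],
    if (length(x$negative)) paste0("; NEGATIVE: ", paste(x$negative, collapse = ","))
    else ""))
  invisible(x)
}

#' Convert an estimate into simulator parameters
#'
#' Refuses estimates with negative flagged weights (the generative model is
#' only defined for non-negative forces).
#'
#' @param est a `bcr_estimate`.
#' @param d_min,T_bar passed to [bcr_params()].
#' @return A [bcr_params()] object.
#' @export
as_bcr_params <- function(est, d_min = est$d_min, T_bar = 10) {
  if (length(est$negative))
    stopf("estimate has negative weight(s) (%s); the simulator refuses them",
          paste(est$negative, collapse = ", "))
  bcr_params(p_I = est$p_I, p_s = est$p_s, p_F = est$p_F,
             mu = est$mu, sigma = est$sigma, X_F = est$X_F,
             d_min = d_min, T_bar = T_bar)
}

#' Subsample (decimate) a trajectory
#'
#' Keeps every `k`-th fix starting with the first; the duration of a
#' retained step is the sum of the `k` constituent durations, so total
#' recording time is preserved up to the trailing remainder. `k = 1` is the
#' identity.
#'
#' @param traj a [bcr_trajectory()].
#' @param k decimation factor (integer >= 1).
#' @return A `bcr_trajectory`.
#' @export
subsample_track <- function(traj, k) {
  k <- as.integer(k)
  if (k < 1) stopf("k must be at least 1")
  if (k == 1) return(traj)
  idx <- seq(1, n_fixes(traj), by = k)
  cs <- cumsum(traj$dt)
  bcr_trajectory(traj$x[idx], traj$y[idx], c(0, diff(cs[idx])), id = traj$id)
}

#' Scale-invariance (subsampling) study
#'
#' Re-estimates the BCR parameters on increasingly decimated versions of a
#' track, holding `d_min` fixed. Inertia and attraction should be nearly
#' invariant in `k` while the immobility weight decays (longer intervals
#' make sub-`d_min` displacements rarer).
#'
#' @param traj a [bcr_trajectory()].
#' @param k_max maximum decimation factor.
#' @param d_min,half_width passed to [estimate_bcr()] (`d_min` is
#'   deliberately not rescaled with `k`).
#' @return A data.frame with one row per `k`: `k`, `n_fixes`, `T_bar`,
#'   `p_I`, `p_s`, `p_F`, `mu`, `sigma`, `degenerate`.
#' @export
scale_invariance_study <- function(traj, k_max = 10, d_min = 10,
                                   half_width = pi / 8) {
  if (k_max < 2) stopf("k_max must be at least 2")
  rows <- lapply(seq_len(k_max), function(k) {
    sub <- subsample_track(traj, k)
    base <- data.frame(k = k, n_fixes = n_fixes(sub),
                       T_bar = if (n_fixes(sub) > 1) mean_sampling_time(sub) else NA_real_)
    est <- tryCatch(
      suppressWarnings(estimate_bcr(sub, d_min = d_min, half_width = half_width)),
      error = function(e) NULL)
    if (is.null(est) || n_fixes(sub) < 3) {
      warnf("k = %d leaves too few fixes for estimation; row marked degenerate", k)
      cbind(base, data.frame(p_I = NA_real_, p_s = NA_real_, p_F = NA_real_,
                             mu = NA_real_, sigma = NA_real_, degenerate = TRUE))
    } else {
      cbind(base, data.frame(p_I = est$p_I, p_s = est$p_s, p_F = est$p_F,
                             mu = est$mu, sigma = est$sigma, degenerate = FALSE))
    }
  })
  do.call(rbind, rows)
}
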