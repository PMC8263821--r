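#' Classify the state of a fix pair
#'
#' A state is the pair (previous fix, current fix). Conflicting states are
#' `H_Is` (the animal was already immobile: displacement at most `d_min`,
#' so no heading is defined) and `H_IF` (the animal was already heading
#' toward the den: its heading within `half_width` of the den direction).
#' `H_Is` takes precedence over `H_IF`. Everything else is the
#' non-conflicting state `H`.
#'
#' @param prev,cur points as length-2 numeric vectors; `prev = NULL` marks
#'   the start of a path (no heading exists), classified `H_Is`.
#' @param params a [bcr_params()] (supplies `X_F` and `d_min`).
#' @param half_width angular half-width of a quadrant, radians.
#' @return One of `"H"`, `"H_IF"`, `"H_Is"`.
#' @export
classify_state <- function(prev, cur, params, half_width = pi / 8) {
  if (is.null(prev)) return("H_Is")
  d <- sqrt(sum((cur - prev)^2))
  if (d <= params$d_min) return("H_Is")
  a2 <- heading(prev, cur)
  a3 <- heading(cur, params$X_F)
  if (abs(angle_difference(a2, a3)) <= half_width) return("H_IF")
  "H"
}

# Branch partition of [0, chi) for a given state label.  Returns the branch
# ("diffusion", "inertia", "immobile", "attraction") chosen by the uniform
# draw x.  Matches the simulator's C++ branch tables exactly.
branch_for_draw <- function(state, x, params) {
  p_I <- params$p_I; p_s <- params$p_s
  if (state == "H") {
    if (x < 8) "diffusion"
    else if (x < 8 + p_I) "inertia"
    else if (x < 8 + p_I + p_s) "immobile"
    else "attraction"
  } else if (state == "H_Is") {
    if (x < 8) "diffusion"
    else if (x < 8 + p_I + p_s) "immobile"
    else "attraction"
  } else { # H_IF
    if (x < 8) "diffusion"
    else if (x < 8 + p_s) "immobile"
    else "inertia"
  }
}

#' Draw one BCR step (reference implementation)
#'
#' Single-step R implementation of the walk dynamics, used as the readable
#' reference against which the compiled simulator is tested. The draw order
#' is: `x ~ U[0, chi)` selects the branch; moving branches then draw
#' `d ~ lnN(mu, sigma)`; the diffusion branch finally draws
#' `alpha_1 ~ U[0, 2*pi)`. The immobile branch consumes no further random
#' numbers. Deterministic headings: inertia repeats the previous heading,
#' attraction points exactly at `X_F`.
#'
#' @param prev,cur previous and current location (`prev = NULL` at the
#'   origin, treated as state `H_Is`).
#' @param params a [bcr_params()].
#' @param half_width angular half-width used in state classification.
#' @param draws optional list overriding random draws (`x`, `d`, `alpha1`)
#'   to force a branch in tests.
#' @return A list with `point` (the new location), `branch` and `state`.
#' @export
bcr_step <- function(prev, cur, params, half_width = pi / 8, draws = list()) {
  state <- classify_state(prev, cur, params, half_width)
  x <- if (!is.null(draws$x)) draws$x else stats::runif(1) * chi_value(params)
  branch <- branch_for_draw(state, x, params)
  if (branch == "immobile") {
    return(list(point = cur, branch = branch, state = state))
  }
  d <- if (!is.null(draws$d)) draws$d else stats::rlnorm(1, params$mu, params$sigma)
  alpha <- switch(branch,
    diffusion = if (!is.null(draws$alpha1)) draws$alpha1 else stats::runif(1) * 2 * pi,
    inertia = heading(prev, cur),
    attraction = heading(cur, params$X_F))
  list(point = cur + d * c(cos(alpha), sin(alpha)), branch = branch,
       state = state)
}

#' Simulate a biased and correlated random walk
#'
#' Iterates the BCR dynamics from an origin. Each step classifies the state
#' of the last fix pair (the origin itself has no heading and is treated
#' under the immobile-state branch table), draws a branch from the partition
#' of `[0, chi)` and displaces by a log-normal step in the chosen direction.
#' Simulated steps carry a constant nominal duration `params$T_bar`.
#'
#' @param params a [bcr_params()].
#' @param n_steps number of steps (the trajectory has `n_steps + 1` fixes).
#' @param origin starting point; defaults to the attractor.
#' @param seed optional integer seed; when given the simulation is fully
#'   reproducible and the caller's RNG state is left untouched.
#' @param exclusion optional polygon (two-column matrix of vertices,
#'   metres): proposed steps landing inside are redrawn. Used to plant
#'   artificial spatial voids in synthetic data.
#' @param max_tries redraw budget per step before the step degenerates to
#'   immobility (only relevant with an exclusion polygon).
#' @return A [bcr_trajectory()]; the number of exclusion redraws is
#'   attached as attribute `"rejected"`.
#' @examples
#' p <- bcr_params(p_I = 0.1, p_s = 1.5, p_F = 0.1)
#' tr <- simulate_bcr(p, 500, seed = 1)
#' @export
simulate_bcr <- function(params, n_steps, origin = params$X_F, seed = NULL,
                         exclusion = NULL, max_tries = 1000L) {
  if (n_steps < 1) stopf("n_steps must be at least 1")
  if (is.null(exclusion)) {
    excl <- matrix(numeric(0), 0, 2)
  } else {
    excl <- as.matrix(exclusion)
    if (ncol(excl) != 2 || nrow(excl) < 3) stopf("exclusion must be a polygon (>= 3 x 2 matrix)")
    if (point_in_polygon(params$X_F[1], params$X_F[2], excl))
      stopf("the attractor lies inside the exclusion polygon")
    if (point_in_polygon(origin[1], origin[2], excl))
      stopf("origin lies inside the exclusion polygon")
  }
  m <- with_seed(seed,
    cpp_simulate_bcr(as.integer(n_steps), origin[1], origin[2],
                     params$p_I, params$p_s, params$p_F,
                     params$mu, params$sigma,
                     params$X_F[1], params$X_F[2],
                     params$d_min, pi / 8,
                     excl, as.integer(max_tries)))
  tr <- bcr_trajectory(m[, 1], m[, 2],
                       dt = c(0, rep(params$T_bar, n_steps)))
  attr(tr, "rejected") <- attr(m, "rejected")
  tr
}

# Even-odd point-in-polygon test (R mirror of the C++ rejection test).
point_in_polygon <- function(x, y, poly) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > y) != (yj > y) && x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}
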