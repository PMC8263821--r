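# Internal helpers: angle arithmetic and scoped RNG.

# Wrap an angle to (-pi, pi].
wrap_angle <- function(a) {
  w <- a - 2 * pi * floor((a + pi) / (2 * pi))
  w[w <= -pi] <- pi  # floor can land on -pi for exact multiples
  w
}

# Signed smallest rotation from b to a, in (-pi, pi].
angle_difference <- function(a, b) wrap_angle(a - b)

#' Convert between the vertex-angle and relative turning-angle conventions
#'
#' Census work states turning angles relative to the incoming direction
#' (0 = straight ahead), while the situation-classification inequalities are
#' written on the geometric vertex angle at the middle fix (pi = straight
#' ahead).  The two are linked by the fixed bijection `phi = pi - vertex`
#' (wrapped to `(-pi, pi]`).
#'
#' @param vertex,phi angles in radians.
#' @return The angle in the other convention, wrapped to `(-pi, pi]`.
#' @export
vertex_to_relative <- function(vertex) wrap_angle(pi - vertex)

#' @rdname vertex_to_relative
#' @export
relative_to_vertex <- function(phi) wrap_angle(pi - phi)

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched.  seed = NULL evaluates as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialise a RNG state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed (< 2^31) from a base seed and an index.
child_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 9973) %% 2147483399 + 1
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
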