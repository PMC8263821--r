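# Shared fixtures built in code.

# Piecewise four-quadrant arctangent, written straight from its case table;
# the independent oracle for heading().
atan2_oracle <- function(y, x) {
  if (x > 0) atan(y / x)
  else if (x < 0 && y >= 0) atan(y / x) + pi
  else if (x < 0 && y < 0) atan(y / x) - pi
  else if (x == 0 && y > 0) pi / 2
  else if (x == 0 && y < 0) -pi / 2
  else 0
}

# A small seeded random walk trajectory.
random_track <- function(n = 50, seed = 1, step = 30, dt = 10) {
  set.seed(seed)
  ang <- runif(n - 1, -pi, pi)
  d <- rlnorm(n - 1, log(step), 0.4)
  bcr_trajectory(cumsum(c(0, d * cos(ang))), cumsum(c(0, d * sin(ang))),
                 c(0, rep(dt, n - 1)))
}

# Reference parameter rows used throughout.
deer1_params <- function(d_min = 10)
  bcr_params(p_I = 0.01, p_s = 2.01, p_F = 0.01, mu = 2.94, sigma = 1.01,
             d_min = d_min)

deer5_params <- function(d_min = 10)
  bcr_params(p_I = 0.22, p_s = 1.66, p_F = 0.24, mu = 3.03, sigma = 1.06,
             d_min = d_min)

# Square exclusion polygon of a given area centred at `center`.
square_exclusion <- function(area = 3e4, center = c(150, 150)) {
  s <- sqrt(area) / 2
  cbind(center[1] + c(-s, s, s, -s), center[2] + c(-s, -s, s, s))
}

# Shoelace area of a polygon given as a two-column matrix.
polygon_area <- function(p) {
  i <- seq_len(nrow(p))
  j <- c(i[-1], i[1])
  abs(sum(p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2])) / 2
}
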