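test_that("state classification follows the conflicting-state rules", {
  p <- bcr_params(d_min = 10, X_F = c(200, 0))
  # short displacement: already immobile, regardless of den geometry
  expect_equal(classify_state(c(0, 0), c(0, 5), p), "H_Is")
  # exact alignment with the den direction
  expect_equal(classify_state(c(0, 0), c(100, 0), p), "H_IF")
  # den at right angle: plain state
  p2 <- bcr_params(d_min = 10, X_F = c(100, 100))
  expect_equal(classify_state(c(0, 0), c(100, 0), p2), "H")
  # origin has no heading
  expect_equal(classify_state(NULL, c(0, 0), p), "H_Is")
  # H_Is takes precedence over H_IF when both hold
  p3 <- bcr_params(d_min = 10, X_F = c(100, 0))
  expect_equal(classify_state(c(0, 0), c(5, 0), p3), "H_Is")
})

test_that("branch tables partition [0, chi) as written, per state", {
  p <- bcr_params(p_I = 0.5, p_s = 1.5, p_F = 0.8)
  b <- function(st, x) bcrwalk:::branch_for_draw(st, x, p)
  expect_equal(b("H", 7.999), "diffusion")
  expect_equal(b("H", 8), "inertia")
  expect_equal(b("H", 8.499), "inertia")
  expect_equal(b("H", 8.5), "immobile")
  expect_equal(b("H", 9.999), "immobile")
  expect_equal(b("H", 10), "attraction")
  # H_Is: inertia mass merges into immobility (no inertia branch)
  expect_equal(b("H_Is", 8), "immobile")
  expect_equal(b("H_Is", 9.999), "immobile")
  expect_equal(b("H_Is", 10), "attraction")
  # H_IF: immobility spans [8, 8 + p_s), the rest goes to the heading branch
  expect_equal(b("H_IF", 8), "immobile")
  expect_equal(b("H_IF", 9.499), "immobile")
  expect_equal(b("H_IF", 9.5), "inertia")
  expect_equal(b("H_IF", 10.7), "inertia")
})

test_that("forced branches give the exact deterministic geometry", {
  p <- bcr_params(p_I = 1, p_s = 1, p_F = 1, X_F = c(1000, 500), d_min = 0)
  prev <- c(0, 0)
  cur <- c(30, 40)
  # inertia: turning angle exactly zero
  st <- bcr_step(prev, cur, p, draws = list(x = 8.5, d = 25))
  expect_equal(st$branch, "inertia")
  expect_equal(turning_angle(prev, cur, st$point), 0)
  # immobility: displacement exactly zero
  st <- bcr_step(prev, cur, p, draws = list(x = 9.5))
  expect_equal(st$branch, "immobile")
  expect_identical(st$point, cur)
  # attraction: exact alignment with the den
  st <- bcr_step(prev, cur, p, draws = list(x = 10.5, d = 60))
  expect_equal(st$branch, "attraction")
  expect_equal(heading(cur, st$point), heading(cur, p$X_F))
})

test_that("compiled simulator reproduces the R reference stepper draw by draw", {
  p <- bcr_params(p_I = 0.4, p_s = 1.2, p_F = 0.6, mu = 3, sigma = 1,
                  X_F = c(100, -50), d_min = 10)
  n <- 300
  tr <- simulate_bcr(p, n, origin = c(0, 0), seed = 99)
  set.seed(99)
  x <- numeric(n + 1)
  y <- numeric(n + 1)
  prev <- NULL
  cur <- c(0, 0)
  for (i in seq_len(n)) {
    st <- bcr_step(prev, cur, p)
    prev <- cur
    cur <- st$point
    x[i + 1] <- cur[1]
    y[i + 1] <- cur[2]
  }
  expect_identical(tr$x, x)
  expect_identical(tr$y, y)
})

test_that("same seed gives a bitwise identical trajectory", {
  p <- deer5_params()
  a <- simulate_bcr(p, 500, seed = 7)
  b <- simulate_bcr(p, 500, seed = 7)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
})

test_that("branch frequencies match their probability masses", {
  p <- bcr_params(p_I = 0.5, p_s = 1.5, p_F = 0.8, X_F = c(500, 0),
                  d_min = 10)
  chi <- chi_value(p)
  n <- 20000
  set.seed(31)
  branches <- character(n)
  states <- character(n)
  prev <- NULL
  cur <- c(0, 0)
  for (i in seq_len(n)) {
    st <- bcr_step(prev, cur, p)
    branches[i] <- st$branch
    states[i] <- st$state
    prev <- cur
    cur <- st$point
  }
  inH <- states == "H"
  nH <- sum(inH)
  probs <- c(diffusion = 8, inertia = p$p_I, immobile = p$p_s,
             attraction = p$p_F) / chi
  for (br in names(probs)) {
    emp <- mean(branches[inH] == br)
    se <- sqrt(probs[[br]] * (1 - probs[[br]]) / nH)
    expect_lt(abs(emp - probs[[br]]), 3 * se + 1e-12)
  }
})

test_that("pure diffusion yields uniform turning angles and log-normal steps", {
  p <- bcr_params(p_I = 0, p_s = 0, p_F = 0, mu = 3, sigma = 1, d_min = 0)
  tr <- simulate_bcr(p, 1e5, seed = 12)
  phi <- turning_angles(tr)
  ks <- suppressWarnings(stats::ks.test(phi, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
  len <- step_lengths(tr)
  m <- exp(3 + 0.5)                      # log-normal mean
  se <- sqrt((exp(1) - 1) * exp(7)) / sqrt(length(len))
  expect_lt(abs(mean(len) - m), 2 * se)
})

test_that("immobile fraction equals p_s / chi in the no-inertia case", {
  p <- bcr_params(p_I = 0, p_s = 100, p_F = 0, d_min = 0)
  tr <- simulate_bcr(p, 20000, seed = 5)
  frac <- mean(step_lengths(tr) == 0)
  pr <- 100 / chi_value(p)
  se <- sqrt(pr * (1 - pr) / 20000)
  expect_lt(abs(frac - pr), 3 * se)
})

test_that("attraction confines the walk", {
  p0 <- bcr_params(p_I = 0, p_s = 0, p_F = 0, d_min = 10)
  p1 <- bcr_params(p_I = 0, p_s = 0, p_F = 2, d_min = 10)
  d0 <- d1 <- numeric(50)
  for (r in 1:50) {
    t0 <- simulate_bcr(p0, 2000, seed = 1000 + r)
    t1 <- simulate_bcr(p1, 2000, seed = 1000 + r)
    d0[r] <- sqrt(t0$x[2001]^2 + t0$y[2001]^2)
    d1[r] <- sqrt(t1$x[2001]^2 + t1$y[2001]^2)
  }
  expect_lt(median(d1), median(d0))
})

test_that("parameter validation refuses negative weights", {
  expect_error(bcr_params(p_I = -0.1), "non-negative")
  expect_error(bcr_params(sigma = 0), "positive")
})
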