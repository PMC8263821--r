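test_that("the attractor is the isobarycentre", {
  sq <- bcr_trajectory(c(0, 0, 2, 2), c(0, 2, 0, 2))
  expect_equal(estimate_attractor(sq), c(1, 1))
  expect_equal(estimate_attractor(bcr_trajectory(5, 7)), c(5, 7))
  set.seed(10)
  cloud <- bcr_trajectory(rnorm(1000, 5), rnorm(1000, 7))
  expect_lt(sqrt(sum((estimate_attractor(cloud) - c(5, 7))^2)),
            3 / sqrt(1000))
})

test_that("situation classification implements the cone and distance rules", {
  # collinear mobile triple, den at right angle: one inertia count only
  tr <- bcr_trajectory(c(0, 50, 100), c(0, 0, 0))
  ct <- classify_situations(tr, X_F = c(0, 500), d_min = 10)
  expect_equal(ct$n_H, 1)
  expect_equal(c(ct$c_I, ct$c_s, ct$c_F), c(1, 0, 0))

  # short outgoing step: counted in s, excluded from I and F
  tr2 <- bcr_trajectory(c(0, 50, 52), c(0, 0, 0))
  ct2 <- classify_situations(tr2, X_F = c(34, 300), d_min = 10)
  expect_equal(ct2$n_H, 1)
  expect_equal(c(ct2$c_I, ct2$c_s, ct2$c_F), c(0, 1, 0))

  # state already heading toward the den: conflicting, never tallied
  tr3 <- bcr_trajectory(c(0, 50, 60), c(0, 0, 0))
  ct3 <- classify_situations(tr3, X_F = c(100, 0), d_min = 10)
  expect_equal(ct3$n_HIF, 1)
  expect_equal(ct3$n_H, 0)

  # immobile incoming step: H_Is
  tr4 <- bcr_trajectory(c(0, 5, 60), c(0, 0, 0))
  ct4 <- classify_situations(tr4, X_F = c(0, 500), d_min = 10)
  expect_equal(ct4$n_HIs, 1)

  expect_error(classify_situations(bcr_trajectory(1:2, 1:2)), "3 fixes")
})

test_that("inversion is the exact algebraic inverse of the forward map", {
  # pure diffusion fixed point
  out <- invert_parameters(1 / 8, 0, 1 / 8)
  expect_equal(c(out$p_I, out$p_s, out$p_F), c(0, 0, 0))
  expect_equal(out$chi, 8)

  # printed Deer-1 weights round-trip exactly
  p <- deer1_params()
  xs <- params_to_proportions(p)
  expect_equal(xs$x2, 2.01 / 10.03)
  inv <- invert_parameters(xs$x1, xs$x2, xs$x3)
  expect_equal(c(inv$p_I, inv$p_s, inv$p_F), c(0.01, 2.01, 0.01),
               tolerance = 1e-12)

  expect_error(invert_parameters(0.5, 0.4, 0.2), "not invertible")

  # property: random non-negative weights survive the round trip to 1e-12
  set.seed(20)
  for (r in 1:1000) {
    w <- runif(3, 0, 3)
    pr <- bcr_params(p_I = w[1], p_s = w[2], p_F = w[3])
    xs <- params_to_proportions(pr)
    inv <- invert_parameters(xs$x1, xs$x2, xs$x3)
    expect_equal(c(inv$p_I, inv$p_s, inv$p_F), w, tolerance = 1e-12)
  }
})

test_that("reduced configurations adjust the cone count in chi", {
  # immobility only: chi = 8 / (1 - x2)
  x2 <- 1.7 / 9.7
  inv <- invert_parameters(x2 = x2, active = "s")
  expect_equal(inv$p_s, 1.7, tolerance = 1e-12)
  expect_true(is.na(inv$p_I))
  # inertia only: chi = 7 / (1 - x1), x1 = (1 + p_I) / (8 + p_I)
  pI <- 0.8
  x1 <- (1 + pI) / (8 + pI)
  inv2 <- invert_parameters(x1 = x1, active = "I")
  expect_equal(inv2$p_I, pI, tolerance = 1e-12)
})

test_that("negative inverted weights are flagged, not clipped", {
  # x1 below the diffusion floor 1/chi forces p_I < 0
  expect_warning(inv <- invert_parameters(0.05, 0.2, 0.2), "negative")
  expect_lt(inv$p_I, 0)
  expect_true("p_I" %in% inv$negative)
  est <- structure(list(p_I = inv$p_I, p_s = inv$p_s, p_F = inv$p_F,
                        mu = 3, sigma = 1, X_F = c(0, 0),
                        negative = inv$negative, d_min = 10),
                   class = "bcr_estimate")
  expect_error(as_bcr_params(est), "refuses")
})

test_that("step-distribution fit is the log-normal ML on mobile steps", {
  d <- rep(exp(3), 10)
  tr <- bcr_trajectory(cumsum(c(0, d)), rep(0, 11))
  fit <- fit_step_distribution(tr, d_min = 10)
  expect_equal(fit$mu, 3)
  expect_equal(fit$sigma, 0)

  set.seed(4)
  d2 <- rlnorm(1e5, 3, 1)
  tr2 <- bcr_trajectory(cumsum(c(0, d2)), rep(0, 1e5 + 1))
  fit2 <- fit_step_distribution(tr2, d_min = 0)
  expect_lt(abs(fit2$mu - 3), 2 / sqrt(1e5))
  expect_lt(abs(fit2$sigma - 1), 2 / sqrt(2 * 1e5))

  # zeros below d_min do not touch the estimate
  d3 <- c(d2[1:1000], rep(0, 300))
  set.seed(5)
  d3 <- sample(d3)
  tr3 <- bcr_trajectory(cumsum(c(0, d3)), rep(0, length(d3) + 1))
  fit_mix <- fit_step_distribution(tr3, d_min = 10)
  fit_ref <- fit_step_distribution(
    bcr_trajectory(cumsum(c(0, d2[1:1000])), rep(0, 1001)), d_min = 10)
  expect_equal(fit_mix$mu, fit_ref$mu)
  expect_equal(fit_mix$sigma, fit_ref$sigma)

  expect_error(fit_step_distribution(
    bcr_trajectory(c(0, 1, 2), c(0, 0, 0)), d_min = 10), "mobile")
})

test_that("estimation recovers pure diffusion and rejects degenerate input", {
  p <- bcr_params(p_I = 0, p_s = 0, p_F = 0, d_min = 0)
  tr <- simulate_bcr(p, 2e4, seed = 3)
  est <- suppressWarnings(estimate_bcr(tr, d_min = 0))
  expect_lt(abs(est$p_I), 0.05)
  expect_lt(abs(est$p_s), 0.05)
  expect_lt(abs(est$p_F), 0.05)

  still <- bcr_trajectory(rep(1, 10), rep(2, 10))
  expect_error(estimate_bcr(still, d_min = 10))
})

test_that("the estimator is invariant under rigid motions", {
  p <- deer5_params()
  tr <- simulate_bcr(p, 3000, seed = 21)
  est <- estimate_bcr(tr, d_min = 10)
  moved <- rigid_transform(tr, angle = 1.1, shift = c(5000, -2000))
  est2 <- estimate_bcr(moved, d_min = 10)
  expect_equal(est2$p_I, est$p_I)
  expect_equal(est2$p_s, est$p_s)
  expect_equal(est2$p_F, est$p_F)
  expect_equal(est2$mu, est$mu)
  expect_equal(est2$sigma, est$sigma)
})

test_that("d_min = 10 inflates the immobility weight (documented bias)", {
  p <- deer5_params()
  tr <- simulate_bcr(p, 3e4, seed = 8)
  est <- estimate_bcr(tr, d_min = 10)
  expect_gt(est$p_s, p$p_s)
})

test_that("subsampling keeps every k-th fix and reconstructs durations", {
  tr <- bcr_trajectory(1:10, rep(0, 10), c(0, rep(1, 9)))
  s2 <- subsample_track(tr, 2)
  expect_equal(s2$x, c(1, 3, 5, 7, 9))
  expect_equal(s2$dt, c(0, rep(2, 4)))
  expect_identical(subsample_track(tr, 1), tr)
  s3 <- subsample_track(tr, 3)
  expect_equal(s3$x, c(1, 4, 7, 10))
  expect_error(subsample_track(tr, 0), "at least 1")
})

test_that("scale-invariance study degrades gracefully and sees no forces in diffusion", {
  p <- bcr_params(p_I = 0, p_s = 0, p_F = 0, d_min = 0)
  tr <- simulate_bcr(p, 5e4, seed = 9)
  tab <- suppressWarnings(scale_invariance_study(tr, k_max = 5, d_min = 0))
  expect_true(all(abs(tab$p_I) < 0.1, na.rm = TRUE))
  expect_true(all(abs(tab$p_F) < 0.1, na.rm = TRUE))

  tiny <- random_track(10, seed = 2)
  w <- capture_warnings(tab2 <- scale_invariance_study(tiny, k_max = 5))
  expect_match(w, "degenerate", all = FALSE)
  expect_true(tab2$degenerate[5])
})
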