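test_that("turning-angle histogram filters immobile legs and normalises", {
  tr <- bcr_trajectory(c(0, 30, 60, 90, 120), rep(0, 5))
  prof <- turning_angle_profile(tr, d_min = 10, n_bins = 36)
  expect_equal(sum(prof$values), 1)
  centre_bin <- ceiling((0 + pi) / (2 * pi / 36))
  expect_equal(prof$values[centre_bin], 1)

  # a 5 m leg drops both triples that touch it
  tr2 <- bcr_trajectory(c(0, 30, 35, 65, 95), rep(0, 5))
  prof2 <- turning_angle_profile(tr2, d_min = 10)
  expect_equal(prof2$meta$n_angles, 1)

  expect_error(turning_angle_profile(bcr_trajectory(c(0, 1, 2), rep(0, 3))),
               "eligible")
})

test_that("diffusion turning angles are flat across bins", {
  p <- bcr_params(p_I = 0, p_s = 0, p_F = 0, d_min = 10)
  tr <- simulate_bcr(p, 1e5, seed = 2)
  prof <- turning_angle_profile(tr, d_min = 10, n_bins = 36)
  expect_lt(max(prof$values) / min(prof$values), 1.5)
})

test_that("home-range isopleths are nested and match the normal oracle", {
  set.seed(2)
  xy <- matrix(rnorm(2e4, 0, 50), ncol = 2)
  tr <- bcr_trajectory(xy[, 1], xy[, 2])
  prof <- home_range_profile(tr)
  expect_true(all(diff(prof$values) <= 0))     # levels are decreasing
  a95 <- prof$values[prof$labels == "95%"]
  exact <- pi * 50^2 * (-2 * log(1 - 0.95))    # analytic 95% ellipse
  expect_lt(abs(a95 / exact - 1), 0.15)
  expect_error(home_range_profile(bcr_trajectory(rep(1, 60), rep(2, 60))),
               "degenerate")
})

test_that("home-range areas scale quadratically under spatial scaling", {
  rt <- random_track(400, seed = 6)
  h <- c(30, 30)
  a1 <- home_range_profile(rt, grid_size = 80, bandwidth = h)
  big <- bcr_trajectory(rt$x * 2, rt$y * 2, rt$dt)
  a2 <- home_range_profile(big, grid_size = 80, bandwidth = 2 * h)
  expect_equal(a2$values, 4 * a1$values, tolerance = 1e-8)
})

test_that("dilation areas match the disk and stadium closed forms", {
  pt <- bcr_trajectory(0, 0)
  prof <- dilation_profile(pt, radii = c(10, 20, 50))
  expect_true(all(abs(prof$values / (pi * c(10, 20, 50)^2) - 1) < 0.05))

  seg <- bcr_trajectory(c(0, 200), c(0, 0))
  r <- c(10, 25, 50)
  stad <- 2 * 200 * r + pi * r^2
  prof2 <- dilation_profile(seg, radii = r)
  expect_true(all(abs(prof2$values / stad - 1) < 0.05))

  rt <- random_track(40, seed = 4)
  prof3 <- dilation_profile(rt, radii = c(5, 10, 20, 40, 80))
  expect_true(all(diff(prof3$values) > 0))     # strictly increasing
})

test_that("still transects count path entries into the sight disk", {
  tr <- bcr_trajectory(c(-500, 500), c(0, 0), c(0, 10))
  p1 <- still_transect_profile(tr, sight = 200, transects = cbind(0, 0))
  expect_equal(p1$values, 1)

  # leave and re-enter the same disk
  tr2 <- bcr_trajectory(c(-500, 0, 500, 0), c(0, 0, 0, 1),
                        c(0, 10, 10, 10))
  p2 <- still_transect_profile(tr2, sight = 200, transects = cbind(0, 0))
  expect_equal(p2$values, 2)

  # fully outside
  p3 <- still_transect_profile(tr, sight = 200, transects = cbind(0, 5000))
  expect_equal(p3$values, 0)

  # sorted descending, reproducible placement
  rt <- random_track(200, seed = 5)
  a <- still_transect_profile(rt, sight = 100, n_transects = 20,
                              placement_seed = 3)
  b <- still_transect_profile(rt, sight = 100, n_transects = 20,
                              placement_seed = 3)
  expect_identical(a$values, b$values)
  expect_true(all(diff(a$values) <= 0))
})

test_that("mobile transects honour the census geometry", {
  # immobile animal at X_1: all 8 linear transects there count it at t = 0
  still <- bcr_trajectory(rep(0, 50), rep(0, 50), c(0, rep(10, 49)))
  m <- mobile_transect_profile(still, sights = 50, speed_multipliers = 1,
                               X_F = c(5000, 5000))
  df <- as.data.frame(m)
  expect_equal(df$value[df$label == "linear_s50_v1"], 8)
  expect_equal(df$value[df$label == "rotational_s50_v1"], 0)

  # animal and one co-moving transect: each transect counts at most one
  # entry; the pack starts on the animal so the total stays 8
  east <- bcr_trajectory(seq(0, 5000, by = 50), rep(0, 101),
                         c(0, rep(10, 100)))
  m2 <- mobile_transect_profile(east, sights = 50, speed_multipliers = 1,
                                X_F = c(0, 50000), respawn_ticks = 1e6)
  d2 <- as.data.frame(m2)
  expect_equal(d2$value[d2$label == "linear_s50_v1"], 8)

  # default sight and speed sets give the full 48-component profile
  rt <- random_track(100, seed = 9)
  full <- mobile_transect_profile(rt)
  expect_equal(length(full$values), 2 * 6 * 4)
  expect_true("linear_s1000_v0.25" %in% full$labels)
  expect_true("rotational_s500_v2" %in% full$labels)
})

test_that("e1/e2 comparator behaves like the paper's error pair", {
  ref <- bcr_profile("x", c(2), "a")
  expect_equal(compare_profiles(ref, ref), list(e1 = 0, e2 = 1, n_sim = 1,
                                                name = "x"))
  sims <- list(bcr_profile("x", 1, "a"), bcr_profile("x", 3, "a"))
  cmp <- compare_profiles(ref, sims)
  expect_equal(cmp$e1, 2)
  expect_equal(cmp$e2, 1)

  ref0 <- bcr_profile("x", c(2, 0), c("a", "b"))
  sim0 <- bcr_profile("x", c(1, 5), c("a", "b"))
  expect_warning(cmp0 <- compare_profiles(ref0, sim0), "zero-reference")
  expect_equal(cmp0$e1, 6)
  expect_equal(cmp0$e2, 0.5)

  expect_error(compare_profiles(ref, bcr_profile("y", 1, "a")),
               "not comparable")
})

test_that("profiles are invariant under rigid translation", {
  rt <- random_track(300, seed = 11)
  shifted <- rigid_transform(rt, shift = c(10000, -3000))
  expect_equal(turning_angle_profile(shifted)$values,
               turning_angle_profile(rt)$values)
  expect_equal(dilation_profile(shifted, radii = c(10, 30))$values,
               dilation_profile(rt, radii = c(10, 30))$values)
  # still transects translate with the bounding box
  expect_equal(still_transect_profile(shifted, placement_seed = 2)$values,
               still_transect_profile(rt, placement_seed = 2)$values)
})
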