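test_that("generated reference is periodic with physiological joint ranges", {
  ref <- generate_reference(0.75)
  expect_identical(ref$n_samples, 101L)
  expect_equal(ref$q[-1, 101], ref$q[-1, 1], tolerance = 1e-12)
  expect_equal(ref$u[, 101], ref$u[, 1], tolerance = 1e-12)
  expect_equal(ref$grf[, 101], ref$grf[, 1], tolerance = 1e-12)
  expect_true(all(ref$sd_q > 0), all(ref$sd_u > 0), all(ref$sd_grf > 0))
  deg <- 180 / pi
  hip <- ref$q["hip_r", ] * deg
  knee <- ref$q["knee_r", ] * deg
  ankle <- ref$q["ankle_r", ] * deg
  expect_gt(min(hip), -30); expect_lt(max(hip), 45)
  expect_gt(min(knee), -5); expect_lt(max(knee), 72)
  expect_gt(min(ankle), -32); expect_lt(max(ankle), 32)
  # left is the right shifted by half a cycle
  expect_equal(unname(ref$q["hip_l", 51]), unname(ref$q["hip_r", 1]),
               tolerance = 1e-6)
})

test_that("cycle-average vertical GRF equals body weight within 1 percent", {
  for (v in c(0.25, 0.75, 1.4)) {
    ref <- generate_reference(v, body_mass = 75.01)
    bw <- 75.01 * 9.80665
    # impulse-momentum: average total vertical force of periodic gait is BW
    tot <- ref$grf["fy_r", ] + ref$grf["fy_l", ]
    avg <- mean(tot[-length(tot)])
    expect_equal(avg, bw, tolerance = 0.01 * bw)
  }
})

test_that("reference speeds are the exact derivatives of the angle curves", {
  err <- vapply(c(1001L, 2001L, 4001L), function(ns) {
    ref <- generate_reference(0.75, n_samples = ns)
    h <- ref$stride_time / (ns - 1)
    idx <- 2:(ns - 1)
    fd <- (ref$q[, idx + 1] - ref$q[, idx - 1]) / (2 * h)
    max(abs(fd - ref$u[, idx]))
  }, numeric(1))
  expect_lt(err[3], 1e-3)
  # central differences converge at second order to the stored speeds
  expect_gt(err[1] / err[2], 3.5)
  expect_gt(err[2] / err[3], 3.5)
})

test_that("generator is deterministic given a seed and validates inputs", {
  r1 <- generate_reference(0.8, seed = 5, jitter = 0.02)
  r2 <- generate_reference(0.8, seed = 5, jitter = 0.02)
  r3 <- generate_reference(0.8, seed = 6, jitter = 0.02)
  expect_identical(r1$q, r2$q)
  expect_false(identical(r1$q, r3$q))
  expect_error(generate_reference(0.1))
  expect_error(generate_reference(2.0))
})

test_that("model-aware reference keeps the stance foot near the ground", {
  m <- the_model()
  ref <- generate_reference(0.75, model = m)
  p <- hemigait:::model_ptr(m)
  pen_target <- (m$body_mass * m$gravity / (2.5 * m$contact$stiffness))^(2 / 3) + 1e-3
  worst_gap <- -Inf; worst_pen <- -Inf
  for (k in seq(1, 101, by = 4)) {
    sp <- hemigait:::.sphere_pos_cpp(p, ref$q[, k])
    bot <- sp$y - sp$radius
    worst_pen <- max(worst_pen, -min(bot))
    worst_gap <- max(worst_gap, min(bot))
  }
  expect_lt(worst_pen, pen_target + 1e-6)   # never deeper than the target
  expect_lt(worst_gap, 0.05)                # some foot always near the ground
})

test_that("reference round-trips through its columnar text format", {
  ref <- generate_reference(0.75, body_mass = 75.01)
  f <- tempfile(fileext = ".tsv")
  write_reference(ref, f)
  ref2 <- read_reference(f)
  expect_equal(ref2$q, ref$q, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ref2$u, ref$u, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ref2$grf, ref$grf, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ref2$sd_q, ref$sd_q, tolerance = 1e-12)
  expect_equal(ref2$stride_time, ref$stride_time)
  unlink(f)
})

test_that("fixture generators are deterministic and validate their kind", {
  f1 <- generate_fixture_trajectory("symmetric_gait", seed = 3)
  f2 <- generate_fixture_trajectory("symmetric_gait", seed = 3)
  expect_identical(f1$traj$X, f2$traj$X)
  expect_error(generate_fixture_trajectory("nope"))
  # custom contact pattern matches its construction under the hard count
  fx <- generate_fixture_trajectory("custom_contact_pattern",
                                    list(n = 201L, n_right = 110L, n_left = 90L))
  hard <- hemigait:::hard_step_time_asymmetry(fx$grf, fx$heel_x)
  expect_equal(hard, (110 - 90) / 200, tolerance = 1e-12)
})

test_that("trajectories round-trip through columnar text and resampling", {
  e <- matrix(runif(24 * 21), 24, 21)
  tr <- make_traj(e, tf = 1.2, disp = 0.9)
  f <- tempfile(fileext = ".tsv")
  write_trajectory(tr, f)
  tr2 <- read_trajectory(f)
  expect_equal(tr2$X, tr$X, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tr2$C, tr$C, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(tr2$tf, tr$tf, tolerance = 1e-9)
  unlink(f)
  # resampling to a refined grid preserves the original nodes
  tr3 <- resample_trajectory(tr, 41L)
  expect_equal(tr3$X[, seq(1, 41, by = 2)], tr$X, tolerance = 1e-6,
               ignore_attr = TRUE)
})
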