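test_that("foot strikes are located by interpolated threshold crossings", {
  n <- 101L
  tt <- seq(0, 1, length.out = n)
  grf <- matrix(0, 4, n)
  # square-ish bursts with known onsets at 0.10 s (right) and 0.60 s (left)
  grf[2, tt >= 0.10 & tt < 0.55] <- 800
  grf[4, tt >= 0.60 & tt < 0.95] <- 800
  ev <- detect_foot_strikes(grf, tt)
  expect_length(ev$right, 1L)
  expect_length(ev$left, 1L)
  expect_lt(abs(ev$right - 0.10), 0.011)  # within one grid interval
  expect_lt(abs(ev$left - 0.60), 0.011)
  expect_false(any(ev$atypical))
})

test_that("degenerate GRF patterns are flagged atypical, not errors", {
  n <- 51L
  tt <- seq(0, 1, length.out = n)
  grf <- matrix(0, 4, n)
  grf[2, ] <- 500                     # right foot never leaves the ground
  ev <- detect_foot_strikes(grf, tt)
  expect_length(ev$right, 0L)
  expect_true(ev$atypical[["right"]])
})

test_that("threshold sensitivity is below one grid interval on a steep rise", {
  n <- 101L
  tt <- seq(0, 1, length.out = n)
  grf <- matrix(0, 4, n)
  grf[2, ] <- pmax(0, (tt - 0.3) * 5000)  # steep ramp through 20 N
  grf[4, tt > 0.7] <- 100
  t20 <- detect_foot_strikes(grf, tt)$right
  t199 <- detect_foot_strikes(grf, tt,
                              config = list(vertical_force_threshold = 19.9))$right
  t201 <- detect_foot_strikes(grf, tt,
                              config = list(vertical_force_threshold = 20.1))$right
  expect_lt(abs(t199 - t20), 0.01)
  expect_lt(abs(t201 - t20), 0.01)
})

test_that("step metrics recover the constructed fixture values", {
  # mirror-symmetric gait
  fx <- generate_fixture_trajectory("symmetric_gait", list(n = 201L, tf = 1.1))
  gm <- step_metrics(fx$traj, heel_x = fx$heel_x, grf = fx$grf)
  expect_equal(gm$sla, 0, tolerance = 0.5)
  expect_equal(gm$sta, 0, tolerance = 0.5)
  expect_equal(gm$st_np + gm$st_p, gm$stride_time, tolerance = 1e-9)
  # constructed asymmetric steps: 0.6 vs 0.4 m gives +20% step-length asymmetry
  fx2 <- generate_fixture_trajectory("offset_steps",
                                     list(n = 201L, tf = 1.0, speed = 1.0,
                                          sl_np = 0.6, sl_p = 0.4,
                                          st_np = 0.55))
  gm2 <- step_metrics(fx2$traj, heel_x = fx2$heel_x, grf = fx2$grf)
  expect_equal(gm2$sla, 20, tolerance = 0.8)
  expect_equal(gm2$sta, sta(0.55, 0.45), tolerance = 1.2)
  expect_equal(gm2$st_np + gm2$st_p, 1.0, tolerance = 1e-9)
})

test_that("side swap negates both asymmetry indices", {
  fx <- generate_fixture_trajectory("offset_steps",
                                    list(n = 201L, tf = 1.0, speed = 1.0,
                                         sl_np = 0.65, sl_p = 0.45,
                                         st_np = 0.58))
  gm <- step_metrics(fx$traj, heel_x = fx$heel_x, grf = fx$grf)
  # swap left/right tracks
  gm_sw <- step_metrics(fx$traj, heel_x = fx$heel_x[2:1, ],
                        grf = fx$grf[c(3, 4, 1, 2), ])
  expect_equal(gm_sw$sla, -gm$sla, tolerance = 1e-6)
  expect_equal(gm_sw$sta, -gm$sta, tolerance = 1e-6)
})

test_that("metrics are stable under grid refinement of the same trajectory", {
  f1 <- generate_fixture_trajectory("offset_steps",
                                    list(n = 101L, tf = 1.0, speed = 1.0,
                                         sl_np = 0.6, sl_p = 0.5))
  f2 <- generate_fixture_trajectory("offset_steps",
                                    list(n = 401L, tf = 1.0, speed = 1.0,
                                         sl_np = 0.6, sl_p = 0.5))
  g1 <- step_metrics(f1$traj, heel_x = f1$heel_x, grf = f1$grf)
  g2 <- step_metrics(f2$traj, heel_x = f2$heel_x, grf = f2$grf)
  expect_equal(g1$sla, g2$sla, tolerance = 0.5)
  expect_equal(g1$sta, g2$sta, tolerance = 1.0)
})

test_that("missing strikes raise an error naming the foot", {
  fx <- generate_fixture_trajectory("symmetric_gait", list(n = 101L))
  grf <- fx$grf; grf[4, ] <- 0
  expect_error(step_metrics(fx$traj, heel_x = fx$heel_x, grf = grf), "left")
})

test_that("condition summary finds the minimum-cost speed with tie and sweep rules", {
  res <- data.frame(weakness = rep(c(0, 0.4), each = 4),
                    speed = rep(c(0.25, 0.75, 1.0, 1.25), 2),
                    cot = c(10, 4, 3.55, 3.5,   # base: optimum at 1.25
                            10, 4, 3.5, 3.55))  # weak: optimum at 1.00
  cs <- condition_summary(res)
  expect_equal(cs$optimal_speed$optimal_speed[cs$optimal_speed$weakness == 0], 1.25)
  expect_equal(cs$optimal_speed$optimal_speed[cs$optimal_speed$weakness == 0.4], 1.00)
  # exact ties go to the slower speed
  res2 <- data.frame(weakness = 0, speed = c(1.0, 1.25), cot = c(3.5, 3.5))
  expect_equal(condition_summary(res2)$optimal_speed$optimal_speed, 1.0)
  # single-speed models are flagged as an insufficient sweep
  res3 <- data.frame(weakness = 0.2, speed = 0.75, cot = 4)
  expect_true(condition_summary(res3)$optimal_speed$insufficient_sweep)
})
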