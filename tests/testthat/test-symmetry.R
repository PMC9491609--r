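test_that("asymmetry indices match the worked cases exactly", {
  expect_equal(sla(0.5, 0.5), 0)
  expect_equal(sla(0.6, 0.4), 20)
  expect_equal(sla(0.4, 0.6), -20)
  expect_equal(sta(0.40, 0.40), 0)
  expect_equal(sta(0.55, 0.45), 10)
  expect_equal(sta(0.40, 0.50), -100 / 9, tolerance = 1e-12)
  expect_error(sla(0, 0))
  expect_error(sta(0, 0))
})

test_that("asymmetry indices are antisymmetric and bounded", {
  set.seed(5)
  for (i in 1:50) {
    v <- runif(2, 0.05, 1)
    expect_equal(sla(v[1], v[2]), -sla(v[2], v[1]))
    expect_lte(abs(sla(v[1], v[2])), 100)
  }
})

test_that("step-length goal is zero without overshoot and grows with it", {
  m <- the_model()
  n <- 41L
  mk <- function(amp) {
    q <- matrix(0, 11, n)
    ph <- seq(0, 1, length.out = n)
    q[2, ] <- 0.94
    q[4, ] <- amp * sin(2 * pi * ph)      # hips swing out of phase
    q[8, ] <- -amp * sin(2 * pi * ph)
    gait_trajectory(1, q, matrix(0, 11, n), matrix(0.01, 24, n),
                    matrix(0.01, 24, n), matrix(0.01, 24, n),
                    matrix(0, 24, n))
  }
  cfg <- symmetry_goal_config(target_stride_length = 1.2, sharpness = 60)
  # small swing: inter-heel distance stays below the 0.6 m target
  expect_lt(step_length_goal(mk(0.15), m, cfg), 1e-4)
  # overshooting swings: penalty positive and increasing with amplitude
  p1 <- step_length_goal(mk(0.8), m, cfg)
  p2 <- step_length_goal(mk(1.1), m, cfg)
  expect_gt(p1, 1e-4)
  expect_gt(p2, p1)
})

test_that("smooth step-length goal approaches its hard-threshold oracle", {
  m <- the_model()
  n <- 41L
  ph <- seq(0, 1, length.out = n)
  q <- matrix(0, 11, n)
  q[2, ] <- 0.94
  q[4, ] <- 0.9 * sin(2 * pi * ph)
  q[8, ] <- -0.9 * sin(2 * pi * ph)
  tr <- gait_trajectory(1, q, matrix(0, 11, n), matrix(0.01, 24, n),
                        matrix(0.01, 24, n), matrix(0.01, 24, n),
                        matrix(0, 24, n))
  heel <- hemigait:::.traj_contact_cpp(hemigait:::model_ptr(m), tr$X)$heel_x
  hard <- hemigait:::hard_step_length_penalty(heel, 0.6, n, 1)
  smooth <- step_length_goal(tr, m, symmetry_goal_config(1.2, sharpness = 400))
  expect_equal(smooth, hard, tolerance = 0.02 * hard)
})

test_that("step-time goal matches the hard node-count oracle", {
  m <- the_model()
  n <- 201L
  # 110 right-contact and 90 left-contact nodes of the 200 counted
  down_r <- c(rep(TRUE, 110), rep(FALSE, 90), TRUE)
  down_l <- c(rep(FALSE, 110), rep(TRUE, 90), FALSE)
  tr <- contact_pattern_traj(m, down_r, down_l)
  cfg <- symmetry_goal_config(1.0, contact_sharpness = 40)
  sts <- step_time_goal(tr, m, cfg)
  hard <- (110 - 90) / 200
  expect_equal(sqrt(sts), abs(hard), tolerance = 0.1 * abs(hard))
  # swapping sides leaves the squared surrogate unchanged
  tr2 <- contact_pattern_traj(m, down_l, down_r)
  expect_equal(step_time_goal(tr2, m, cfg), sts, tolerance = 1e-6)
  # balanced 100/100 pattern scores ~zero
  bal <- contact_pattern_traj(m, c(rep(TRUE, 100), rep(FALSE, 100), TRUE),
                              c(rep(FALSE, 100), rep(TRUE, 100), FALSE))
  expect_lt(step_time_goal(bal, m, cfg), 1e-4)
})

test_that("symmetry goal config validates inputs and zero weights are inert", {
  expect_error(symmetry_goal_config(-1))
  expect_error(symmetry_goal_config(1, w_sl = -2))
  m <- the_model()
  n <- 15L
  e <- matrix(0.05, 24, n)
  tr <- make_traj(e, tf = 1, disp = 0.75, a = matrix(0.05, 24, n))
  nlp0 <- transcribe(m, 0.75, "effort", collocation_grid(n))
  nlpz <- transcribe(m, 0.75, "symmetry", collocation_grid(n),
                     symmetry = symmetry_goal_config(1.0, w_sl = 0, w_st = 0))
  expect_equal(nlp_objective(nlpz, tr)$total, nlp_objective(nlp0, tr)$total,
               tolerance = 1e-12)
})
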