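test_that("metabolic rates match the independent equation transcription", {
  m <- the_model()
  tr <- random_muscle_traj()   # 25 nodes x 24 muscles = 600 random states
  for (choice in c("umberger", "bhargava")) {
    got <- metabolic_rate(tr, m, metabolic_config(choice))
    want <- oracle_rates(tr, m, choice)
    expect_lt(max(abs(got - want) / pmax(abs(want), 1e-8)), 1e-8)
  }
})

test_that("an idle muscle consumes only the small activation-level heat", {
  m <- the_model()
  n <- 11L
  a <- matrix(0.001, 24, n)
  q <- matrix(0, 11, n); q[1, ] <- seq(0, 1, length.out = n); q[2, ] <- 2.0
  tr <- gait_trajectory(1, q, matrix(0, 11, n), a, matrix(0, 24, n), a,
                        matrix(0, 24, n))
  rate <- metabolic_rate(tr, m, metabolic_config("umberger"))
  active <- metabolic_rate(random_muscle_traj(n), m, metabolic_config("umberger"))
  expect_lt(max(rate), 0.05 * max(active))
})

test_that("mass-proportional heat terms scale linearly with muscle mass", {
  m <- the_model()
  m2 <- m
  m2$cache <- new.env(parent = emptyenv())
  for (i in seq_along(m2$muscles))
    m2$muscles[[i]]$muscle_mass <- 2 * m2$muscles[[i]]$muscle_mass
  n <- 11L
  # isometric states: no fiber work, heat only (heat is per-kg times mass)
  a <- matrix(0.4, 24, n)
  q <- matrix(0, 11, n); q[1, ] <- seq(0, 1, length.out = n); q[2, ] <- 2.0
  tr <- gait_trajectory(1, q, matrix(0, 11, n), a, matrix(0.2, 24, n), a,
                        matrix(0, 24, n))
  r1 <- metabolic_rate(tr, m, metabolic_config("umberger"))
  r2 <- metabolic_rate(tr, m2, metabolic_config("umberger"))
  expect_equal(r2, 2 * r1, tolerance = 1e-10)
})

test_that("weakness changes only force-dependent terms on a fixed trajectory", {
  m <- the_model()
  wk <- apply_weakness(m, 0.4)
  tr <- random_muscle_traj()
  r_base <- metabolic_rate(tr, m, metabolic_config("umberger"))
  r_weak <- metabolic_rate(tr, wk, metabolic_config("umberger"))
  # right limb muscles are untouched entirely
  expect_equal(r_weak[1:12, ], r_base[1:12, ], tolerance = 1e-12)
  # left limb: muscle masses fixed, only tendon-force scaling differs
  expect_false(isTRUE(all.equal(r_weak[13:24, ], r_base[13:24, ])))
})

test_that("mechanical work reproduces the sine-power analytic case", {
  n <- 2001L
  tf <- 2 * pi
  q <- matrix(0, 11, n); q[1, ] <- seq(0, 1, length.out = n); q[2, ] <- 1
  tr <- gait_trajectory(tf, q, matrix(0, 11, n), matrix(0.1, 24, n),
                        matrix(0.1, 24, n), matrix(0.1, 24, n),
                        matrix(0, 24, n))
  power <- matrix(0, 24, n)
  power[1, ] <- sin(tr$times)
  mw <- mechanical_work(tr, power = power, body_mass = 1, displacement = 1)
  expect_equal(mw$w_pos[["total"]], 2, tolerance = 2e-3)
  expect_equal(mw$w_neg[["total"]], -2, tolerance = 2e-3)
  expect_equal(mw$w_pos[["np"]], 2, tolerance = 2e-3)   # muscle 1 is right-side
  expect_equal(mw$w_neg[["p"]], 0)
  # all-positive power has zero negative work
  mw2 <- mechanical_work(tr, power = abs(power), body_mass = 1, displacement = 1)
  expect_equal(mw2$w_neg[["total"]], 0)
})

test_that("trapezoid work integration matches a fine-grid oracle", {
  set.seed(12)
  n <- 501L
  tf <- 1.3
  tt <- seq(0, tf, length.out = n)
  cf <- rnorm(4)
  pw <- function(t) cf[1] * sin(2 * pi * t / tf) + cf[2] * cos(4 * pi * t / tf) +
    cf[3] * sin(6 * pi * t / tf) + cf[4]
  q <- matrix(0, 11, n); q[1, ] <- tt; q[2, ] <- 1
  tr <- gait_trajectory(tf, q, matrix(0, 11, n), matrix(0.1, 24, n),
                        matrix(0.1, 24, n), matrix(0.1, 24, n), matrix(0, 24, n))
  power <- matrix(0, 24, n); power[5, ] <- pw(tt)
  mw <- mechanical_work(tr, power = power, body_mass = 70, displacement = 1.3)
  tfine <- seq(0, tf, length.out = 100001)
  wpos_fine <- sum(pmax(pw(tfine), 0)) * tf / 100000
  expect_equal(mw$w_pos[["total"]], wpos_fine, tolerance = 1e-3 * abs(wpos_fine))
})

test_that("cost of transport arithmetic and scaling", {
  expect_equal(cost_of_transport(70, 70, 1), 1)
  expect_equal(cost_of_transport(100, 70, 2), cost_of_transport(100, 70, 1) / 2)
  expect_error(cost_of_transport(10, 70, 0))
})

test_that("integrated activation matches the analytic and loop oracles", {
  n <- 41L
  a <- matrix(0.001, 24, n)
  q <- matrix(0, 11, n); q[1, ] <- seq(0, 1, length.out = n); q[2, ] <- 1
  tr <- gait_trajectory(1, q, matrix(0, 11, n), a, a, a, matrix(0, 24, n))
  ia <- integrated_activation(tr)
  expect_equal(ia[["np"]], 0.012, tolerance = 1e-12)
  expect_equal(ia[["total"]], 0.024, tolerance = 1e-12)
  # random activations against an explicit loop
  set.seed(4)
  tr$X[23:46, ] <- runif(24 * n)
  ia2 <- integrated_activation(tr)
  acc <- 0
  for (mm in 1:24) {
    y <- tr$X[22 + mm, ]
    acc <- acc + sum(diff(tr$times) * (y[-n] + y[-1]) / 2)
  }
  expect_equal(ia2[["total"]], acc, tolerance = 1e-12)
})

test_that("unknown metabolic model choice is rejected", {
  expect_error(metabolic_config("other"))
})

test_that("energy report is additive across limbs", {
  m <- the_model()
  tr <- random_muscle_traj()
  en <- energy_report(tr, m)
  expect_equal(en$energy[["total"]] - en$basal,
               en$energy[["np"]] + en$energy[["p"]], tolerance = 1e-10)
  expect_gte(en$w_pos[["total"]], 0)
  expect_lte(en$w_neg[["total"]], 0)
  expect_equal(en$w_pos[["total"]], en$w_pos[["np"]] + en$w_pos[["p"]],
               tolerance = 1e-10)
})
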