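test_that("characteristic curves have the documented landmarks", {
  cv <- characteristic_curves(1.0, 0.0, 1.0)
  expect_equal(cv$active_fl, 1, tolerance = 2e-3)       # peak at optimal length
  expect_equal(cv$fv, 1, tolerance = 5e-3)              # multiplier ~1 at rest
  expect_equal(cv$passive_fl, 0, tolerance = 1e-12)     # no passive force
  expect_lt(characteristic_curves(tendon_strain_length = 1.0)$tendon_fl, 0.01)
  expect_lt(characteristic_curves(tendon_strain_length = 0.95)$tendon_fl, 0)
  # peak location: values on either side of optimal are lower
  side <- characteristic_curves(c(0.9, 1.1))$active_fl
  expect_true(all(side < 1))
})

test_that("curve values match an independent transcription of the equations", {
  set.seed(42)
  lm <- runif(100, 0.4, 1.7)
  vm <- runif(100, -1.2, 1.2)
  lt <- runif(100, 0.95, 1.08)
  cv <- characteristic_curves(lm, vm, lt)
  # direct transcription, coded independently of the compiled implementation
  b <- cbind(c(0.815, 1.055, 0.162, 0.063),
             c(0.433, 0.717, -0.030, 0.200),
             c(0.100, 1.000, 0.354, 0.000))
  afl <- rowSums(sapply(1:3, function(i)
    b[1, i] * exp(-0.5 * (lm - b[2, i])^2 / (b[3, i] + b[4, i] * lm)^2)))
  pfl <- (exp(4.0 * (lm - 1) / 0.6) - 1) / (exp(4.0) - 1)
  dd <- c(-0.318, -8.149, -0.374, 0.886)
  fv <- dd[1] * log(dd[2] * vm + dd[3] + sqrt((dd[2] * vm + dd[3])^2 + 1)) + dd[4]
  ften <- 0.2 * exp(35 * (lt - 0.995)) - 0.25
  expect_equal(cv$active_fl, afl, tolerance = 1e-12)
  expect_equal(cv$passive_fl, pfl, tolerance = 1e-12)
  expect_equal(cv$fv, fv, tolerance = 1e-12)
  expect_equal(cv$tendon_fl, ften, tolerance = 1e-12)
})

test_that("curves are C1-smooth (derivatives consistent under FD refinement)", {
  xs <- seq(0.3, 1.9, by = 0.05)
  d1 <- (characteristic_curves(xs + 1e-5)$active_fl -
           characteristic_curves(xs - 1e-5)$active_fl) / 2e-5
  d2 <- (characteristic_curves(xs + 1e-6)$active_fl -
           characteristic_curves(xs - 1e-6)$active_fl) / 2e-6
  expect_lt(max(abs(d1 - d2) / (1 + abs(d2))), 1e-3)
})

test_that("activation dynamics: fixed point, signs, and time constant", {
  expect_equal(activation_dynamics(0.5, 0.5), 0, tolerance = 1e-12)
  expect_gt(activation_dynamics(1, 0.001), 0)
  expect_lt(activation_dynamics(0.1, 0.9), 0)
  # rate scale when fully driven: (e - a) / tau_a
  expect_equal(activation_dynamics(1, 0.001), (1 - 0.001) / 0.015,
               tolerance = 1e-6)
  # step response reaches 63.2% of the gap in about one activation tau
  a <- 0.001; dt <- 1e-5; t <- 0
  target <- 0.001 + (1 - exp(-1)) * (1 - 0.001)
  while (a < target) {
    a <- a + dt * activation_dynamics(1, a)
    t <- t + dt
  }
  expect_equal(t, 0.015, tolerance = 0.02)
})

test_that("tendon equilibrium residual has the bisection-oracle root", {
  m <- the_model()
  g <- muscle_geometry(m, rep(0, 11), rep(0, 11))
  for (im in c(3, 8, 12)) {   # gluteus maximus, soleus, flexor digitorum brevis
    res <- function(ft) tendon_equilibrium_residual(m, im, a = 0.5,
                                                    f_tendon_norm = ft,
                                                    df_tendon_norm = 0,
                                                    l_mt = g$lmt[im], v_mt = 0)
    root <- uniroot(res, c(1e-9, 1.8), tol = 1e-14)$root
    expect_lt(abs(res(root)), 1e-10)
    # perturbing the tendon force off equilibrium flips the residual sign
    expect_lt(res(root + 0.1) * res(root - min(0.1, root / 2)), 0)
  }
})

test_that("zero-force tendon state at slack length gives ~zero residual", {
  m <- the_model()
  # at the calibration pose every fiber sits at optimal length with the
  # tendon at slack, so zero tendon force balances (almost) zero fiber force
  cal <- m$calibration_pose
  qcal <- c(0, 0.9, 0, cal$hip, cal$knee, cal$ankle, cal$toe,
            cal$hip, cal$knee, cal$ankle, cal$toe)
  g <- muscle_geometry(m, qcal, rep(0, 11))
  r <- tendon_equilibrium_residual(m, 1:24, a = 0.001, f_tendon_norm = 0,
                                   df_tendon_norm = 0, l_mt = g$lmt, v_mt = 0)
  expect_lt(max(abs(r)), 5e-3)
})

test_that("equilibrium root is unique on random physiological states", {
  m <- the_model()
  set.seed(7)
  ok <- 0L
  for (i in 1:100) {
    im <- sample(24, 1)
    q <- runif(11, -0.3, 0.3); q[2] <- 0.95
    u <- runif(11, -1, 1)
    g <- muscle_geometry(m, q, u)
    a <- runif(1, 0.05, 1)
    grid <- seq(1e-6, 1.8, length.out = 200)
    r <- tendon_equilibrium_residual(m, im, a, grid, 0, g$lmt[im], g$vmt[im])
    ok <- ok + as.integer(sum(diff(sign(r)) != 0) == 1L)
  }
  expect_gte(ok, 99L)
})

test_that("moment arms equal minus the length derivative (path consistency)", {
  m <- the_model()
  fl <- hemigait:::model_flat(m)
  q0 <- c(0, 0.95, 0.1, 0.2, 0.3, -0.1, 0.05, -0.2, 0.4, 0.2, 0.1)
  eps <- 1e-7
  for (j in 4:11) {
    qp <- q0; qp[j] <- qp[j] + eps
    dl <- (muscle_geometry(m, qp)$lmt - muscle_geometry(m, q0)$lmt) / eps
    expect_equal(unname(dl), -fl$arms[, j], tolerance = 1e-6)
  }
})
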