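test_that("freefall and zero-input accelerations are exact", {
  m <- the_model()
  q <- rep(0, 11); q[2] <- 2.0   # airborne
  qdd <- skeletal_dynamics(m, q, rep(0, 11))
  expect_equal(qdd[1], 0, tolerance = 1e-6)
  expect_equal(qdd[2], -m$gravity, tolerance = 1e-6)
  # zero gravity, zero forces, zero velocity -> zero acceleration
  cfg <- yaml::read_yaml(system.file("extdata", "planar_walker.yaml",
                                     package = "hemigait"))
  cfg$gravity <- 0
  m0 <- hemigait:::build_gait_model(cfg)
  # toe angles stay at zero: the passive toe return spring is the only
  # configuration-dependent force besides gravity and contact
  q0 <- c(0, 2.0, 0.1, 0.3, 0.5, -0.2, 0, -0.3, 0.2, 0.1, 0)
  expect_lt(max(abs(skeletal_dynamics(m0, q0, rep(0, 11)))), 1e-8)
})

test_that("static two-footed stance balances body weight symmetrically", {
  m <- the_model()
  bw <- m$body_mass * m$gravity
  f <- function(h) {
    grf <- contact_forces(m, c(0, h, rep(0, 9)))$grf
    grf[["fy_r"]] + grf[["fy_l"]] - bw
  }
  h0 <- uniroot(f, c(0.85, 0.96), tol = 1e-12)$root
  cc <- contact_forces(m, c(0, h0, rep(0, 9)))
  expect_equal(cc$grf[["fy_r"]], cc$grf[["fy_l"]], tolerance = 1e-9)
  expect_equal(cc$grf[["fy_r"]] + cc$grf[["fy_l"]], bw, tolerance = 1e-6)
  # Newton for the whole body: summed mass-weighted vertical accelerations
  # equal (total contact force - weight)/..., i.e. zero at the balanced pose
  qdd <- skeletal_dynamics(m, c(0, h0, rep(0, 9)), rep(0, 11))
  tau <- inverse_dynamics(m, c(0, h0, rep(0, 9)), rep(0, 11), qdd)
  expect_lt(abs(tau[2]), 1e-6)   # no net vertical actuation needed
  expect_lt(abs(tau[1]), 1e-6)   # nor horizontal
})

test_that("contact force vanishes with clearance and grows with depth", {
  m <- the_model()
  cc <- contact_forces(m, c(0, 0.945 + 0.1, rep(0, 9)))
  expect_lt(max(abs(cc$sphere_fy)), 1e-3)   # 10 cm above ground
  depths <- seq(-0.02, 0.02, length.out = 41)
  fy <- vapply(depths, function(d)
    contact_forces(m, c(0, 0.945 - d, rep(0, 9)))$grf[["fy_r"]], numeric(1))
  expect_true(all(diff(fy) > 0))            # strictly increasing with depth
  expect_true(all(fy > -1e-9))              # never pulls downward
})

test_that("contact force field is smooth across the touchdown transition", {
  m <- the_model()
  heights <- seq(0.90, 0.99, by = 0.004)   # spans loaded to airborne
  d_of <- function(eps) vapply(heights, function(h) {
    (contact_forces(m, c(0, h + eps, rep(0, 9)))$grf[["fy_r"]] -
       contact_forces(m, c(0, h - eps, rep(0, 9)))$grf[["fy_r"]]) / (2 * eps)
  }, numeric(1))
  d1 <- d_of(1e-5); d2 <- d_of(1e-6)
  expect_lt(max(abs(d1 - d2) / (1 + abs(d2))), 1e-3)
})

test_that("ballistic dynamics agree with a fine-step RK4 oracle", {
  m <- the_model()
  # raised-leg airborne pose: passive swing under gravity, no contact
  q <- c(0, 2.0, 0, 0.6, 0.4, -0.1, 0, -0.3, 0.1, 0, 0)
  u <- rep(0, 11)
  f <- function(q, u) skeletal_dynamics(m, q, u)
  rk4_step <- function(q, u, dt) {
    k1u <- f(q, u)
    k2u <- f(q + dt / 2 * u, u + dt / 2 * k1u)
    k3u <- f(q + dt / 2 * (u + dt / 2 * k1u), u + dt / 2 * k2u)
    k4u <- f(q + dt * (u + dt / 2 * k2u), u + dt * k3u)
    list(q = q + dt / 6 * (u + 2 * (u + dt / 2 * k1u) +
                             2 * (u + dt / 2 * k2u) + (u + dt * k3u)),
         u = u + dt / 6 * (k1u + 2 * k2u + 2 * k3u + k4u))
  }
  # oracle: very fine RK4; check the package's implicit integrator against it
  fine <- list(q = q, u = u)
  for (i in 1:2000) fine <- rk4_step(fine$q, fine$u, 1e-4)
  X <- hs_integrate(function(t, x) c(x[12:22], f(x[1:11], x[12:22])),
                    c(q, u), tf = 0.2, n = 81)
  expect_lt(max(abs(X[1:11, 81] - fine$q)), 1e-4)
})

test_that("forward and inverse dynamics are mutually consistent", {
  m <- the_model()
  fl <- hemigait:::model_flat(m)
  set.seed(3)
  q <- c(0, 0.93, runif(9, -0.2, 0.2))
  u <- runif(11, -0.5, 0.5)
  ft <- runif(24, 0, 0.3)
  qdd <- skeletal_dynamics(m, q, u, ft)
  tau <- inverse_dynamics(m, q, u, qdd, contact = TRUE, gravity = TRUE)
  tau_mus <- as.numeric(t(fl$arms) %*% (ft * fl$fmax))
  tau_pass <- -fl$jdamp * u - fl$jstiff * q
  expect_equal(tau, tau_mus + tau_pass, tolerance = 1e-6)
})

test_that("pelvis displacement is the net forward travel", {
  e <- matrix(0.1, 24, 11)
  tr0 <- make_traj(e, tf = 1, disp = 0)
  expect_equal(pelvis_displacement(tr0), 0)
  tr <- make_traj(e, tf = 1, disp = 1.2)
  expect_equal(pelvis_displacement(tr), 1.2, tolerance = 1e-12)
})
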