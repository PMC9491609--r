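test_that("effort objective matches analytic constant and polynomial cases", {
  # one muscle at e = 0.5 for 2 s over 1 m: 0.5^3 * 2 / 1
  e <- matrix(0, 24, 21); e[1, ] <- 0.5
  expect_equal(effort_objective(make_traj(e, tf = 2, disp = 1)), 0.25,
               tolerance = 1e-12)
  # all 24 muscles at e = 1 for 1 s over 2 m: 24 / 2
  e <- matrix(1, 24, 21)
  expect_equal(effort_objective(make_traj(e, tf = 1, disp = 2)), 12,
               tolerance = 1e-12)
  # e(t) = t on [0,1]: integral of t^3 is 1/4 (Simpson is exact for cubics)
  e <- matrix(0, 24, 21); e[1, ] <- seq(0, 1, length.out = 21)
  expect_equal(effort_objective(make_traj(e, tf = 1, disp = 1)), 0.25,
               tolerance = 1e-9)
  # positive displacement required
  expect_error(effort_objective(make_traj(e, tf = 1, disp = 0)))
})

test_that("tracking objective reduces to the effort objective at zero deviation", {
  m <- the_model()
  ref <- generate_reference(0.75, model = m)
  g <- reference_guess(m, ref, 0.75, n_nodes = 21L)
  # a trajectory identical to the reference kinematics with matched GRFs has
  # only the GRF mismatch term; compare against the independent loop-summed
  # computation instead of spot values
  nlp <- transcribe(m, 0.75, "tracking", collocation_grid(21L), reference = ref)
  parts <- nlp_objective(nlp, g)
  expect_equal(parts$total - parts$track, parts$effort, tolerance = 1e-9)
  oracle <- tracking_objective(g, ref, m, w_kin = 1, w_grf = 1)
  expect_equal(parts$total, oracle, tolerance = 1e-6 * max(1, oracle))
  # with zero weights the tracking part vanishes identically
  nlp0 <- transcribe(m, 0.75, "tracking", collocation_grid(21L),
                     reference = ref, tracking_weights = c(0, 0))
  expect_equal(nlp_objective(nlp0, g)$total, parts$effort, tolerance = 1e-10)
})

test_that("zero-sigma reference is rejected", {
  m <- the_model()
  ref <- generate_reference(0.75, model = m)
  ref$sd_q[3] <- 0
  expect_error(transcribe(m, 0.75, "tracking", collocation_grid(21L),
                          reference = ref), "standard deviation")
})

test_that("transcription is fourth-order on a linear ODE", {
  f <- function(t, x) -x
  err <- vapply(c(11L, 21L, 41L), function(n) {
    X <- hs_integrate(f, 1, tf = 1, n = n)
    max(abs(X[1, ] - exp(-seq(0, 1, length.out = n))))
  }, numeric(1))
  expect_gte(err[1] / err[2], 8)
  expect_gte(err[2] / err[3], 8)
  expect_lt(err[3], 1e-8)
})

test_that("minimum-effort double integrator matches the closed form", {
  # min int u^2 with x1' = x2, x2' = u, from (0,0) to (1,0) in 1 s:
  # u*(t) = 6 - 12 t, x1*(t) = 3 t^2 - 2 t^3
  prob <- ode_problem(f = function(t, x, u) c(x[2], u),
                      nx = 2, nu = 1, tf = 1, x0 = c(0, 0), xf = c(1, 0),
                      lagrange = function(t, x, u) u^2)
  nlp <- transcribe(prob, collocation_grid(21L))
  res <- solve_ode_nlp(nlp, control = solver_control(tol = 1e-6, mu0 = 10,
                                                     outer_max = 15,
                                                     inner_maxit = 3000))
  expect_true(res$converged)
  tt <- res$times
  expect_lt(max(abs(res$X[1, ] - (3 * tt^2 - 2 * tt^3))), 1e-4)
  inner <- 2:20
  expect_lt(max(abs(res$U[1, inner] - (6 - 12 * tt[inner]))), 1e-2)
  expect_equal(res$objective, 12, tolerance = 1e-4)
})

test_that("periodicity residuals vanish on a constant trajectory", {
  m <- the_model()
  n <- 15L
  e <- matrix(0.05, 24, n)
  tr <- make_traj(e, tf = 1, disp = NULL, a = matrix(0.05, 24, n))
  nlp <- transcribe(m, 0.75, "effort", collocation_grid(n))
  con <- nlp_constraints(nlp, tr)
  ndef <- (n - 1L) * 70L
  peri <- con[(ndef + 24L * n + 1L):length(con)]
  # all channels periodic except pelvis_tx which must advance by v * tf
  expect_lt(max(abs(peri[-1])), 1e-10)
  expect_equal(peri[1], -0.75 * 1, tolerance = 1e-10)
})

test_that("augmented-Lagrangian gradient matches the exported Jacobian", {
  m <- the_model()
  n <- 11L
  set.seed(11)
  q <- matrix(0, 11, n); q[1, ] <- seq(0, 0.5, length.out = n); q[2, ] <- 1.2
  q[4:11, ] <- runif(8 * n, -0.2, 0.2)
  u <- matrix(runif(11 * n, -0.5, 0.5), 11, n); u[1, ] <- 0.7
  tr <- gait_trajectory(0.8, q, u, matrix(0.2, 24, n), matrix(0.1, 24, n),
                        matrix(0.2, 24, n), matrix(0.3, 24, n))
  nlp <- transcribe(m, 0.7, "effort", collocation_grid(n))
  op <- hemigait:::nlp_ptr(nlp)
  z <- hemigait:::pack_z(tr, nlp$scales)
  ncon <- hemigait:::.ocp_dims_cpp(op)$ncon
  lam <- runif(ncon, -0.01, 0.01); mu <- 2.5
  al <- hemigait:::.ocp_al_cpp(op, z, lam, mu, TRUE)
  kk <- hemigait:::.ocp_kkt_cpp(op, z)
  J <- Matrix::sparseMatrix(i = kk$i + 1L, j = kk$j + 1L, x = kk$x,
                            dims = c(ncon, length(z)))
  g2 <- kk$grad_obj + as.numeric(Matrix::crossprod(J, lam + mu * kk$con))
  expect_lt(max(abs(al$gradient - g2)), 1e-8 * max(1, max(abs(al$gradient))))
  expect_equal(al$max_violation, max(abs(kk$con)), tolerance = 1e-12)
})

test_that("solver failure paths return non-converged results, not errors", {
  m <- the_model()
  n <- 11L
  e <- matrix(0.05, 24, n)
  tr <- make_traj(e, tf = 1, disp = 0.75, a = matrix(0.05, 24, n))
  nlp <- transcribe(m, 0.75, "effort", collocation_grid(n))
  nlp$lb[5] <- 10; nlp$ub[5] <- -10   # inconsistent bounds
  res <- solve_nlp(nlp, tr)
  expect_s3_class(res, "gait_ocp_result")
  expect_false(res$converged)
})

test_that("select_best keeps the least-objective converged solution", {
  mk <- function(obj, conv, label) structure(
    list(objective_value = obj, converged = conv, guess_label = label),
    class = "gait_ocp_result")
  sols <- list(mk(3.1, TRUE, "a"), mk(2.9, TRUE, "b"), mk(3.0, TRUE, "c"))
  expect_identical(select_best(sols)$guess_label, "b")
  # convergence gates selection even when the objective is lower
  sols2 <- list(mk(2.5, FALSE, "lowest"), mk(3.0, TRUE, "ok"))
  expect_identical(select_best(sols2)$guess_label, "ok")
  expect_identical(select_best(list(mk(1, TRUE, "only")))$guess_label, "only")
  expect_error(select_best(list(mk(1, FALSE, "x"))), "no converged")
})

test_that("odd node counts are enforced for Simpson pairing", {
  expect_error(collocation_grid(50L))
  expect_error(collocation_grid(9L))
  expect_silent(collocation_grid(51L))
})
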