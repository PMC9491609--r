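#' Collocation grid
#'
#' Evenly spaced node grid for Hermite-Simpson transcription. The node count
#' must be odd (so that composite Simpson quadrature pairs intervals) and at
#' least 11; the stride time is a free variable bounded to `[0.3, 2]` s.
#'
#' @param n_nodes number of collocation nodes (default 51 for the reduced
#'   profile; 201 for full-resolution runs).
#' @param tf_bounds bounds on the free final time, s.
#' @return a list with the grid description.
#' @export
collocation_grid <- function(n_nodes = 51L, tf_bounds = c(0.3, 2)) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 11L || n_nodes %% 2L == 0L)
    stop("`n_nodes` must be odd and at least 11")
  stopifnot(tf_bounds[1] > 0, tf_bounds[1] < tf_bounds[2])
  list(n_nodes = n_nodes, tf_bounds = tf_bounds)
}

#' Muscular effort objective
#'
#' Integral over the stride of the summed cubed muscle excitations, divided by
#' the forward pelvis displacement (a muscle-fatigue proxy). Quadrature is
#' composite Simpson on the node grid, consistent with the transcription.
#'
#' @param traj a `gait_trajectory`.
#' @return the scalar effort objective.
#' @export
effort_objective <- function(traj) {
  disp <- pelvis_displacement(traj)
  if (disp <= 0) stop("pelvis displacement must be positive")
  e <- traj_e(traj)
  n <- traj$n
  h <- traj$tf / (n - 1)
  e0 <- e[, -n, drop = FALSE]
  e1 <- e[, -1, drop = FALSE]
  em <- (e0 + e1) / 2
  sum(h / 6 * (e0^3 + 4 * em^3 + e1^3)) / disp
}

simpson_weights <- function(n, h) {
  # composite Simpson coefficients 1, 4, 2, 4, ..., 2, 4, 1 (n odd)
  w <- rep(c(2, 4), length.out = n)
  w[1] <- w[n] <- 1
  w * h / 3
}

#' Tracking objective
#'
#' Effort objective plus integrated SD-normalized squared deviations of the 11
#' coordinate values, 11 speeds, and 4 ground-reaction-force channels from a
#' reference gait, evaluated at the node phases.
#'
#' @param traj a `gait_trajectory`.
#' @param ref a `reference_gait` (see [generate_reference()]).
#' @param model a `gait_model` (needed to evaluate the model's GRFs).
#' @param w_kin,w_grf weights on the kinematic and GRF deviation terms.
#' @return the scalar tracking objective.
#' @export
tracking_objective <- function(traj, ref, model, w_kin = 1, w_grf = 1) {
  if (any(ref$sd_q <= 0) || any(ref$sd_u <= 0) || any(ref$sd_grf <= 0))
    stop("reference standard deviations must be positive")
  n <- traj$n
  rs <- reference_at_phases(ref, seq(0, 1, length.out = n))
  ct <- .traj_contact_cpp(model_ptr(model), traj$X)
  w <- simpson_weights(n, traj$tf / (n - 1))
  q <- traj_q(traj); u <- traj_u(traj)
  dev <- numeric(n)
  for (k in seq_len(n)) {
    dq <- (q[-1, k] - rs$q[-1, k]) / ref$sd_q[-1]   # forward position untracked
    du <- (u[-1, k] - rs$u[-1, k]) / ref$sd_u[-1]
    dg <- (ct$grf[, k] - rs$grf[, k]) / ref$sd_grf
    dev[k] <- w_kin * (sum(dq^2) + sum(du^2)) + w_grf * sum(dg^2)
  }
  unname(effort_objective(traj) + sum(w * dev))
}

# ---------------------------------------------------------------- transcribe

#' Transcribe an optimal-control gait problem
#'
#' Builds the sparse nonlinear program for one periodic stride: decision
#' variables are all node states, controls, and the free final time;
#' constraints are compressed Hermite-Simpson defects for the skeletal,
#' activation, and tendon-force dynamics, the implicit tendon equilibrium at
#' every node, variable bounds, and stride periodicity (with the forward
#' pelvis position advancing by speed times stride time).
#'
#' @param model a `gait_model`.
#' @param speed target average gait speed, m/s.
#' @param objective `"effort"` (nominal), `"tracking"`, or `"symmetry"`
#'   (effort plus smooth step-length/step-time symmetry goals).
#' @param grid a [collocation_grid()].
#' @param reference a `reference_gait`, required for `"tracking"`.
#' @param tracking_weights weights `w_kin`, `w_grf` of the tracking terms.
#' @param symmetry a [symmetry_goal_config()], required for `"symmetry"`.
#' @param q_bounds 11 x 2 matrix overriding the model's coordinate bounds
#'   (used by the tracking stage to keep the search in a corridor around the
#'   reference kinematics).
#' @return an object of class `gait_nlp`.
#' @export
transcribe <- function(model, ...) UseMethod("transcribe")

#' @rdname transcribe
#' @export
transcribe.gait_model <- function(model, speed,
                                  objective = c("effort", "tracking", "symmetry"),
                                  grid = collocation_grid(),
                                  reference = NULL,
                                  tracking_weights = c(w_kin = 1, w_grf = 1),
                                  symmetry = NULL, q_bounds = NULL, ...) {
  objective <- match.arg(objective)
  n <- grid$n_nodes
  sc <- traj_scales()
  opts <- list(n_nodes = n, speed = speed, sx = sc$sx, su = sc$su,
               sd = sc$sd, stf = sc$stf, obj_mode = switch(objective, effort = 0L,
                                               tracking = 1L, symmetry = 2L))
  if (objective == "tracking") {
    if (is.null(reference)) stop("tracking transcription requires a reference gait")
    if (any(reference$sd_q <= 0) || any(reference$sd_u <= 0) ||
        any(reference$sd_grf <= 0))
      stop("reference standard deviations must be positive")
    rs <- reference_at_phases(reference, seq(0, 1, length.out = n))
    opts$qref <- rs$q; opts$uref <- rs$u; opts$grfref <- rs$grf
    opts$sigq <- reference$sd_q; opts$sigu <- reference$sd_u
    opts$siggrf <- reference$sd_grf
    opts$w_track_kin <- unname(tracking_weights[1])
    opts$w_track_grf <- unname(tracking_weights[2])
  }
  if (objective == "symmetry") {
    if (is.null(symmetry)) stop("symmetry transcription requires a goal config")
    opts$w_sl <- symmetry$w_sl
    opts$w_st <- symmetry$w_st
    opts$target_step <- symmetry$target_step_length
    opts$sharp_sl <- symmetry$sharpness
    opts$f_thresh <- symmetry$contact_force_threshold
    opts$sharp_contact <- symmetry$contact_sharpness
    opts$sharp_lead <- symmetry$lead_sharpness
  }
  # scaled bounds on the decision vector
  bq <- model$coordinates
  if (!is.null(q_bounds)) {
    bq[, "lower"] <- pmax(bq[, "lower"], q_bounds[, 1])
    bq[, "upper"] <- pmin(bq[, "upper"], q_bounds[, 2])
  }
  xlb <- c(bq[, "lower"], bq[, "speed_lower"], rep(0.001, 24), rep(0, 24)) / sc$sx
  xub <- c(bq[, "upper"], bq[, "speed_upper"], rep(1, 24), rep(1.8, 24)) / sc$sx
  clb <- c(rep(0.001, 24), rep(-1000, 24)) / sc$su
  cub <- c(rep(1, 24), rep(1000, 24)) / sc$su
  lb <- c(rep(xlb, n), rep(clb, n), grid$tf_bounds[1] / sc$stf)
  ub <- c(rep(xub, n), rep(cub, n), grid$tf_bounds[2] / sc$stf)
  lb[1] <- ub[1] <- 0  # pin the initial forward pelvis position
  opts$lb <- lb; opts$ub <- ub
  nlp <- structure(list(model = model, speed = speed, objective = objective,
                        grid = grid, opts = opts, lb = lb, ub = ub,
                        scales = sc, cache = new.env(parent = emptyenv())),
                   class = "gait_nlp")
  if (objective == "tracking") {
    # diagonal Gauss-Newton curvature of the kinematic tracking quadratic
    w <- simpson_weights(n, 1.2 / (n - 1))   # nominal stride-time weights
    hd <- numeric(n * (.NX + .NU) + 1L)
    wk <- opts$w_track_kin
    for (k in seq_len(n)) {
      iq <- (k - 1L) * .NX + 2:11
      iu <- (k - 1L) * .NX + 13:22
      hd[iq] <- 2 * wk * w[k] * (sc$sx[2:11] / opts$sigq[-1])^2
      hd[iu] <- 2 * wk * w[k] * (sc$sx[13:22] / opts$sigu[-1])^2
    }
    assign("hdiag", hd, envir = nlp$cache)
  }
  nlp
}

nlp_ptr <- function(nlp) {
  p <- nlp$cache$ptr
  if (!is.null(p) && !xptr_alive(p, function(pp) .ocp_dims_cpp(pp))) p <- NULL
  if (is.null(p)) {
    p <- .ocp_build_cpp(model_ptr(nlp$model), nlp$opts)
    assign("ptr", p, envir = nlp$cache)
  }
  p
}

#' Constraint values of a transcribed problem
#'
#' @param nlp a `gait_nlp`.
#' @param traj a `gait_trajectory` on the problem's grid.
#' @return the scaled constraint vector (defects, tendon equilibrium,
#'   periodicity), zero at feasibility.
#' @export
nlp_constraints <- function(nlp, traj) {
  .ocp_constraints_cpp(nlp_ptr(nlp), pack_z(traj, nlp$scales))
}

#' Objective parts of a transcribed problem
#'
#' @param nlp a `gait_nlp`.
#' @param traj a `gait_trajectory`.
#' @return list with `total`, `effort`, `track`, `sls`, `sts`.
#' @export
nlp_objective <- function(nlp, traj) {
  .ocp_objective_cpp(nlp_ptr(nlp), pack_z(traj, nlp$scales))
}

#' @method print gait_nlp
#' @export
print.gait_nlp <- function(x, ...) {
  d <- .ocp_dims_cpp(nlp_ptr(x))
  cat(sprintf(paste0("gait NLP: %d nodes, %d variables, %d equality",
                     " constraints, objective '%s', speed %.2f m/s\n"),
              d$n_nodes, d$nz, d$ncon, x$objective, x$speed))
  invisible(x)
}

# ------------------------------------------------------------------- solver

#' Solver options for the augmented-Lagrangian method
#'
#' The transcribed program is solved by an augmented-Lagrangian outer loop.
#' Inner subproblems are minimized first with bound-constrained L-BFGS-B
#' (cheap, robust far from the solution), then with a damped Gauss-Newton
#' method using the exact sparse constraint Jacobian (fast near feasibility);
#' multipliers are updated when the constraint violation falls sufficiently,
#' otherwise the penalty is increased.
#'
#' @param tol feasibility tolerance on the scaled constraint violation
#'   (default 1e-3, the reduced-resolution profile; use 1e-4 for
#'   full-resolution replication runs).
#' @param outer_max maximum multiplier/penalty updates.
#' @param inner_maxit L-BFGS-B iteration cap per subproblem.
#' @param newton_maxit Gauss-Newton iteration cap per subproblem.
#' @param lbfgs_outers number of initial outer iterations using L-BFGS-B
#'   before switching to Gauss-Newton.
#' @param mu0,mu_mult,mu_max initial penalty, its growth factor, and cap.
#' @param factr L-BFGS-B relative-progress stop (`optim` convention).
#' @param verbose print per-outer-iteration progress.
#' @return list of solver settings.
#' @export
solver_control <- function(tol = 1e-3, outer_max = 30L, inner_maxit = 400L,
                           newton_maxit = 25L, lbfgs_outers = 0L,
                           mu0 = 1e4, mu_mult = 4, mu_max = 3e5,
                           factr = 1e9, verbose = FALSE) {
  list(tol = tol, outer_max = outer_max, inner_maxit = inner_maxit,
       newton_maxit = newton_maxit, lbfgs_outers = lbfgs_outers,
       mu0 = mu0, mu_mult = mu_mult, mu_max = mu_max, factr = factr,
       verbose = verbose)
}

# one damped Gauss-Newton pass on the augmented Lagrangian:
# H = mu J'J + (lm + ridge) I on the free variables, projected line search
newton_inner <- function(op, z, lambda, mu, lb, ub, maxit, verbose = FALSE,
                         hdiag = NULL) {
  nz <- length(z)
  lm <- 1e-4
  al_value <- function(zz) .ocp_al_cpp(op, zz, lambda, mu, FALSE)$value
  nfe <- 0L
  for (it in seq_len(maxit)) {
    kk <- .ocp_kkt_cpp(op, z)
    ncon <- length(kk$con)
    J <- Matrix::sparseMatrix(i = kk$i + 1L, j = kk$j + 1L, x = kk$x,
                              dims = c(ncon, nz))
    y <- lambda + mu * kk$con
    g <- kk$grad_obj + as.numeric(Matrix::crossprod(J, y))
    phi0 <- kk$objective + sum(lambda * kk$con) + 0.5 * mu * sum(kk$con^2)
    atl <- z <= lb + 1e-9 & g > 0
    atu <- z >= ub - 1e-9 & g < 0
    free <- which(!(atl | atu))
    pg <- g; pg[atl | atu] <- 0
    if (max(abs(pg)) < 1e-6 * (1 + abs(phi0))) break
    Jf <- J[, free, drop = FALSE]
    H <- mu * Matrix::crossprod(Jf)
    if (!is.null(hdiag)) H <- H + Matrix::Diagonal(length(free), hdiag[free])
    dg <- Matrix::diag(H)
    ok_step <- FALSE
    for (try in 1:8) {
      Hd <- H + Matrix::Diagonal(length(free), lm * (dg + 1))
      p_free <- tryCatch(
        as.numeric(Matrix::solve(Matrix::Cholesky(Hd, LDL = FALSE, perm = TRUE, super = TRUE),
                                 -g[free])),
        error = function(e) NULL)
      if (is.null(p_free)) { lm <- lm * 10; next }
      # predicted reduction of the quadratic model
      pred <- -(sum(g[free] * p_free) +
                  0.5 * sum(p_free * as.numeric(Hd %*% p_free)))
      alpha <- 1
      improved <- FALSE
      for (ls in 1:10) {
        zn <- z
        zn[free] <- zn[free] + alpha * p_free
        zn <- pmin(pmax(zn, lb), ub)
        phin <- al_value(zn); nfe <- nfe + 1L
        if (is.finite(phin) && phin < phi0 - 1e-12 * abs(phi0)) {
          z <- zn; improved <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (improved) {
        actual <- phi0 - phin
        ratio <- if (pred > 0) actual / (alpha * pred) else 1
        if (alpha == 1 && ratio > 0.25) lm <- max(lm / 3, 1e-9)
        else if (alpha < 0.25) lm <- lm * 4
        if (verbose)
          cat(sprintf("    GN %2d: phi %.6e -> %.6e, alpha %.3g, lm %.1e, |pg| %.2e\n",
                      it, phi0, phin, alpha, lm, max(abs(pg))))
        ok_step <- TRUE
        break
      }
      lm <- lm * 10
      if (lm > 1e8) break
    }
    if (!ok_step) break
    if (phi0 - phin < 1e-8 * (1 + abs(phi0)) && it > 3) break
  }
  list(par = z, fevals = nfe)
}

#' Solve a transcribed gait problem
#'
#' @param nlp a `gait_nlp` from [transcribe()].
#' @param guess a `gait_trajectory` initial guess on the problem's grid.
#' @param control a [solver_control()] list.
#' @param guess_label label recorded in the solution (used by
#'   [select_best()] tie-breaking).
#' @return an object of class `gait_ocp_result`: the trajectory, objective
#'   parts, convergence flag, and the maximum (scaled) constraint violation.
#' @export
solve_nlp <- function(nlp, guess, control = solver_control(),
                      guess_label = "guess") {
  op <- nlp_ptr(nlp)
  d <- .ocp_dims_cpp(op)
  z <- pack_z(guess, nlp$scales)
  if (length(z) != d$nz)
    return(failed_result(nlp, guess, guess_label, "dimension mismatch"))
  lb <- nlp$lb; ub <- nlp$ub
  if (any(lb > ub))
    return(failed_result(nlp, guess, guess_label, "inconsistent bounds"))
  z <- pmin(pmax(z, lb), ub)
  lambda <- numeric(d$ncon)
  mu <- control$mu0
  eval0 <- .ocp_al_cpp(op, z, lambda, mu, FALSE)
  eta <- max(eval0$max_violation / 4, control$tol)
  best <- NULL
  obj_prev <- Inf
  converged <- FALSE
  iters <- 0L
  for (outer in seq_len(control$outer_max)) {
    if (outer <= control$lbfgs_outers) {
      fn <- function(zz) .ocp_al_cpp(op, zz, lambda, mu, FALSE)$value
      gr <- function(zz) .ocp_al_cpp(op, zz, lambda, mu, TRUE)$gradient
      opt <- tryCatch(
        optim(z, fn, gr, method = "L-BFGS-B", lower = lb, upper = ub,
              control = list(maxit = control$inner_maxit,
                             factr = control$factr, lmm = 20)),
        error = function(e) NULL)
      if (!is.null(opt)) { z <- opt$par; iters <- iters + opt$counts[1] }
    } else {
      opt <- tryCatch(newton_inner(op, z, lambda, mu, lb, ub,
                                   control$newton_maxit, control$verbose,
                                   hdiag = nlp$cache$hdiag),
                      error = function(e) NULL)
      if (!is.null(opt)) { z <- opt$par; iters <- iters + opt$fevals }
    }
    if (is.null(opt)) break
    ev <- .ocp_al_cpp(op, z, lambda, mu, FALSE)
    viol <- ev$max_violation
    if (control$verbose)
      cat(sprintf("  outer %2d: J = %.5f, viol = %.3e, mu = %.1e\n",
                  outer, ev$objective, viol, mu))
    if (is.null(best) || viol < best$viol * 0.999 ||
        (viol <= control$tol && ev$objective < best$objective))
      best <- list(z = z, viol = viol, objective = ev$objective)
    con <- .ocp_constraints_cpp(op, z)
    lam_cap <- 3e4
    if (viol <= eta) {
      # sufficient feasibility progress: first-order multiplier update
      lambda <- pmin(pmax(lambda + mu * con, -lam_cap), lam_cap)
      eta <- max(viol / 4, control$tol)
      if (viol <= control$tol &&
          abs(ev$objective - obj_prev) <= 1e-5 * (1 + abs(ev$objective))) {
        converged <- TRUE
        break
      }
    } else if (mu < control$mu_max) {
      # insufficient progress: raise the penalty, keep multipliers
      mu <- min(mu * control$mu_mult, control$mu_max)
    } else {
      # penalty at its cap: fall back to (safeguarded) multiplier updates
      lambda <- pmin(pmax(lambda + mu * con, -lam_cap), lam_cap)
      eta <- max(viol, control$tol)
    }
    obj_prev <- ev$objective
  }
  if (!is.null(best) && best$viol <= control$tol) z <- best$z
  traj <- unpack_z(z, d$n_nodes, nlp$scales)
  parts <- nlp_objective(nlp, traj)
  viol <- max(abs(nlp_constraints(nlp, traj)))
  structure(list(trajectory = traj, objective_value = parts$total,
                 parts = parts, converged = converged && viol <= control$tol,
                 max_constraint_violation = viol, iterations = iters,
                 guess_label = guess_label, nlp = nlp),
            class = "gait_ocp_result")
}

failed_result <- function(nlp, guess, guess_label, why) {
  structure(list(trajectory = guess, objective_value = Inf,
                 parts = list(total = Inf), converged = FALSE,
                 max_constraint_violation = Inf, iterations = 0L,
                 guess_label = guess_label, failure = why, nlp = nlp),
            class = "gait_ocp_result")
}

#' @method print gait_ocp_result
#' @export
print.gait_ocp_result <- function(x, ...) {
  cat(sprintf("collocation solve [%s]: %s, objective %.5f, max violation %.2e\n",
              x$guess_label,
              if (x$converged) "converged" else "NOT converged",
              x$objective_value, x$max_constraint_violation))
  invisible(x)
}

#' Select the best converged solution
#'
#' Among solutions of the same condition started from different initial
#' guesses, returns the converged one with the least objective value. Ties
#' (within 1e-12) are broken by guess order.
#'
#' @param solutions list of `gait_ocp_result` objects.
#' @return the selected solution.
#' @export
select_best <- function(solutions) {
  if (length(solutions) == 0L) stop("no solutions supplied")
  ok <- vapply(solutions, function(s) isTRUE(s$converged), logical(1))
  if (!any(ok)) stop("no converged solutions among the ", length(solutions),
                     " supplied")
  cand <- solutions[ok]
  obj <- vapply(cand, `[[`, numeric(1), "objective_value")
  cand[[which.min(obj)]]
}
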