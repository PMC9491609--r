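#' Build an initial guess from a reference gait
#'
#' Samples the reference kinematics at the node phases, overrides the forward
#' pelvis position with uniform travel at the target speed, and fills the
#' muscle channels consistently: activations at a small constant, normalized
#' tendon forces at their isometric equilibrium for the sampled kinematics
#' (per-node bisection on the equilibrium residual), and tendon-force
#' derivatives from finite differences of that equilibrium trace.
#'
#' @param model a `gait_model`.
#' @param ref a `reference_gait`.
#' @param speed target speed (m/s).
#' @param n_nodes collocation node count.
#' @param a0 baseline activation for the guess.
#' @return a `gait_trajectory`.
#' @export
reference_guess <- function(model, ref, speed, n_nodes = 51L, a0 = 0.05) {
  n <- n_nodes
  ph <- seq(0, 1, length.out = n)
  rs <- reference_at_phases(ref, ph)
  tf <- ref$stride_time
  q <- rs$q; u <- rs$u
  q[1, ] <- speed * ph * tf
  u[1, ] <- speed
  p <- model_ptr(model)
  fl <- model_flat(model)
  h <- tf / (n - 1)
  # accelerations by periodic central differences of the reference speeds
  udot <- u
  idx <- 2:(n - 1)
  udot[, idx] <- (u[, idx + 1] - u[, idx - 1]) / (2 * h)
  udot[, 1] <- udot[, n] <- (u[, 2] - u[, n - 1]) / (2 * h)
  # muscle torques required at the joints (inverse dynamics net of the
  # passive joint structures), distributed over the muscles by bounded
  # ridge-regularized least squares at every node
  A <- t(fl$arms * fl$fmax)[4:11, , drop = FALSE]    # 8 x 24
  ft <- matrix(0, 24, n)
  a <- matrix(a0, 24, n)
  ridge <- 30
  AtA <- crossprod(A) + diag(ridge, 24)
  for (k in seq_len(n)) {
    tau <- .inv_dyn_cpp(p, q[, k], u[, k], udot[, k], TRUE, TRUE)
    tau <- tau + fl$jdamp * u[, k] + fl$jstiff * q[, k]
    tj <- tau[4:11]
    fobj <- function(x) {
      r <- as.numeric(A %*% x) - tj
      0.5 * sum(r^2) + 0.5 * ridge * sum((x - 0.02)^2)
    }
    gobj <- function(x) as.numeric(AtA %*% x) - as.numeric(crossprod(A, tj)) -
      ridge * 0.02
    o <- optim(rep(0.05, 24), fobj, gobj, method = "L-BFGS-B",
               lower = 0, upper = 1.5, control = list(maxit = 80))
    ft[, k] <- o$par
  }
  # light smoothing of the tendon-force traces; close the cycle
  ft <- t(apply(ft, 1, function(y) {
    y[n] <- y[1]
    sm <- stats::filter(c(y[n - 1], y[-n], y[1], y[2]), rep(1 / 3, 3))
    as.numeric(sm)[2:(n + 1)]
  }))
  ft[is.na(ft)] <- 0.02
  ft[, n] <- ft[, 1]
  dft <- ft
  dft[, idx] <- (ft[, idx + 1] - ft[, idx - 1]) / (2 * h)
  dft[, 1] <- dft[, n] <- (ft[, 2] - ft[, n - 1]) / (2 * h)
  dft <- pmin(pmax(dft, -900), 900)
  # activations by inverting the fiber equilibrium (affine in activation)
  for (k in seq_len(n)) {
    g <- .muscle_geometry_cpp(p, q[, k], u[, k])
    r0 <- .tendon_residual_cpp(p, 1:24, rep(0, 24), ft[, k], dft[, k],
                               g$lmt, g$vmt)
    r1 <- .tendon_residual_cpp(p, 1:24, rep(1, 24), ft[, k], dft[, k],
                               g$lmt, g$vmt)
    aa <- -r0 / pmax(r1 - r0, 1e-6)
    a[, k] <- pmin(pmax(aa, 0.001), 1)
  }
  a[, n] <- a[, 1]
  # light smoothing of activations, then excitations that reproduce the
  # activation rate through the first-order dynamics
  a <- t(apply(a, 1, function(y) {
    y[n] <- y[1]
    sm <- stats::filter(c(y[n - 1], y[-n], y[1], y[2]), rep(1 / 3, 3))
    pmin(pmax(as.numeric(sm)[2:(n + 1)], 0.001), 1)
  }))
  a[, n] <- a[, 1]
  adot <- a
  adot[, idx] <- (a[, idx + 1] - a[, idx - 1]) / (2 * h)
  adot[, 1] <- adot[, n] <- (a[, 2] - a[, n - 1]) / (2 * h)
  e <- a + adot * ifelse(adot > 0, fl$tau_a, fl$tau_d)
  e <- pmin(pmax(e, 0.001), 1)
  gait_trajectory(tf, q, u, a, ft, e = e, dft = dft)
}

#' Fit a periodic gait
#'
#' The package's central fitting function: transcribes the periodic
#' optimal-control problem for one stride at a target speed and solves it.
#' Objective variants: `"tracking"` (effort plus reference tracking, used to
#' build initial guesses), `"nominal"` (muscular effort alone), `"sl_sym"`
#' (effort plus the smooth step-length symmetry goal, weight 8), and
#' `"sl_st_sym"` (both symmetry goals, weights 8 and 5).
#'
#' @param model a `gait_model` (weakness applied via [apply_weakness()]).
#' @param speed target average speed, m/s.
#' @param objective one of `"nominal"`, `"tracking"`, `"sl_sym"`,
#'   `"sl_st_sym"`.
#' @param n_nodes collocation nodes (odd; 51 default reduced profile).
#' @param guess optional `gait_trajectory` initial guess (resampled to the
#'   grid if needed); defaults to a reference-based guess.
#' @param reference a `reference_gait`; generated at `speed` if missing and
#'   needed.
#' @param target_stride_length stride-length target for the symmetry goals
#'   (from the matching nominal solution).
#' @param weights optional named overrides: `w_sl`, `w_st`, `w_kin`, `w_grf`.
#' @param control a [solver_control()].
#' @param stiffness_continuation increasing sequence of contact-stiffness
#'   factors ending at 1; earlier stages solve with softened contact (to a
#'   loose tolerance) and warm-start the next, which greatly improves
#'   convergence from coarse guesses. Use `1` to disable.
#' @param guess_label label stored with the result.
#' @return an object of class `gait_solution`.
#' @export
fit_gait <- function(model, speed,
                     objective = c("nominal", "tracking", "sl_sym", "sl_st_sym"),
                     n_nodes = 51L, guess = NULL, reference = NULL,
                     target_stride_length = NULL, weights = NULL,
                     control = solver_control(),
                     stiffness_continuation = 1,
                     guess_label = NULL) {
  objective <- match.arg(objective)
  grid <- collocation_grid(n_nodes)
  if (objective == "tracking") {
    if (is.null(reference))
      reference <- generate_reference(speed, model = model)
    # the tracking stage keeps the stride time near the reference's
    grid <- collocation_grid(n_nodes,
                             tf_bounds = reference$stride_time * c(0.85, 1.15))
  }
  w <- list(w_sl = 8, w_st = 5, w_kin = 1, w_grf = 1)
  if (!is.null(weights)) w <- modifyList(w, as.list(weights))
  track_bounds <- if (objective == "tracking") {
    # corridor around the reference kinematics: blocks drift into sustained
    # flight or folded postures far from the tracked gait
    delta <- c(Inf, 0.04, 0.25, rep(0.35, 8))
    cbind(apply(reference$q, 1, min) - delta,
          apply(reference$q, 1, max) + delta)
  }
  make_nlp <- function(mod) switch(objective,
    nominal = transcribe(mod, speed, "effort", grid),
    tracking = transcribe(mod, speed, "tracking", grid, reference = reference,
                          tracking_weights = c(w$w_kin, w$w_grf),
                          q_bounds = track_bounds),
    sl_sym = ,
    sl_st_sym = {
      if (is.null(target_stride_length))
        stop("symmetry objectives need `target_stride_length` from the nominal solution")
      scfg <- symmetry_goal_config(target_stride_length,
                                   w_sl = w$w_sl,
                                   w_st = if (objective == "sl_sym") 0 else w$w_st)
      transcribe(mod, speed, "symmetry", grid, symmetry = scfg)
    })
  nlp <- make_nlp(model)
  if (is.null(guess)) {
    if (is.null(reference))
      reference <- generate_reference(speed, model = model)
    guess <- reference_guess(model, reference, speed, n_nodes)
    if (is.null(guess_label)) guess_label <- "reference"
  } else {
    if (guess$n != n_nodes) guess <- resample_trajectory(guess, n_nodes)
    if (is.null(guess_label)) guess_label <- "warm start"
  }
  t0 <- proc.time()[3]
  stages <- sort(unique(c(pmin(stiffness_continuation, 1), 1)))
  for (sf in stages[stages < 1]) {
    soft <- model
    soft$cache <- new.env(parent = emptyenv())
    soft$contact$stiffness <- model$contact$stiffness * sf
    ctl_soft <- control
    ctl_soft$tol <- max(control$tol, 5e-3)
    ctl_soft$outer_max <- min(control$outer_max, 12L)
    stage <- solve_nlp(make_nlp(soft), guess, ctl_soft,
                       guess_label = guess_label)
    guess <- stage$trajectory
  }
  if (objective == "tracking" && w$w_grf > 0 && is.null(attr(guess, "staged"))) {
    # stage the tracking solve: settle kinematic tracking + dynamics first,
    # then add the (much stiffer) GRF tracking term
    nlp_kin <- transcribe(model, speed, "tracking", grid, reference = reference,
                          tracking_weights = c(w$w_kin, 0),
                          q_bounds = track_bounds)
    ctl_kin <- control
    ctl_kin$tol <- max(control$tol, 5e-3)
    ctl_kin$outer_max <- min(control$outer_max, 15L)
    stage <- solve_nlp(nlp_kin, guess, ctl_kin, guess_label = guess_label)
    guess <- stage$trajectory
  }
  res <- solve_nlp(nlp, guess, control, guess_label = guess_label)
  elapsed <- proc.time()[3] - t0
  sol <- structure(list(
    trajectory = res$trajectory,
    model = model,
    condition = list(speed = speed, objective = objective,
                     weakness = model$weakness,
                     weights = w, n_nodes = n_nodes,
                     target_stride_length = target_stride_length),
    objective_value = res$objective_value,
    parts = res$parts,
    converged = res$converged,
    max_constraint_violation = res$max_constraint_violation,
    iterations = res$iterations,
    guess_label = res$guess_label,
    nlp = nlp,
    seconds = elapsed,
    call = match.call()),
    class = "gait_solution")
  sol$metrics <- tryCatch(step_metrics(sol$trajectory, model),
                          error = function(e) NULL)
  sol
}

#' @method print gait_solution
#' @export
print.gait_solution <- function(x, ...) {
  w <- x$condition$weakness
  cat(sprintf("gait solution: %s objective, %.2f m/s, weakness L %.0f%%/R %.0f%%\n",
              x$condition$objective, x$condition$speed,
              100 * w[["left"]], 100 * w[["right"]]))
  cat(sprintf("  %s; objective %.5f; max constraint violation %.2e; %d inner iterations (%.0f s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$objective_value, x$max_constraint_violation, x$iterations,
              x$seconds))
  if (!is.null(x$metrics))
    cat(sprintf("  SLA %+.2f%%, STA %+.2f%%, stride %.3f m / %.3f s\n",
                x$metrics$sla, x$metrics$sta, x$metrics$stride_length,
                x$metrics$stride_time))
  invisible(x)
}

#' Summarize a gait solution
#'
#' Computes the spatiotemporal metrics and the full energetic report.
#'
#' @param object a `gait_solution`.
#' @param metabolic_model `"umberger"` (default) or `"bhargava"`.
#' @param ... unused.
#' @return a `summary.gait_solution` list.
#' @method summary gait_solution
#' @export
summary.gait_solution <- function(object, metabolic_model = "umberger", ...) {
  en <- energy_report(object$trajectory, object$model,
                      metabolic_config(metabolic_model))
  out <- list(solution = object, metrics = object$metrics, energy = en)
  class(out) <- "summary.gait_solution"
  out
}

#' @method print summary.gait_solution
#' @export
print.summary.gait_solution <- function(x, ...) {
  print(x$solution)
  if (!is.null(x$metrics)) print(x$metrics)
  print(x$energy)
  invisible(x)
}

#' @method coef gait_solution
#' @export
coef.gait_solution <- function(object, ...) {
  m <- object$metrics
  c(objective = object$objective_value,
    effort = object$parts$effort,
    sla = if (!is.null(m)) m$sla else NA_real_,
    sta = if (!is.null(m)) m$sta else NA_real_,
    stride_length = if (!is.null(m)) m$stride_length else NA_real_,
    stride_time = object$trajectory$tf)
}

#' @method residuals gait_solution
#' @export
residuals.gait_solution <- function(object, ...) {
  nlp_constraints(object$nlp, object$trajectory)
}

#' @method plot gait_solution
#' @export
plot.gait_solution <- function(x, which = c("kinematics", "grf", "muscle"), ...) {
  which <- match.arg(which)
  traj <- x$trajectory
  ph <- 100 * seq(0, 1, length.out = traj$n)
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  if (which == "kinematics") {
    graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
    q <- traj_q(traj) * 180 / pi
    for (j in c("hip", "knee", "ankle", "toe")) {
      r <- q[paste0(j, "_r") == coordinate_names, ]
      l <- q[paste0(j, "_l") == coordinate_names, ]
      graphics::matplot(ph, cbind(r, l), type = "l", lty = 1:2,
                        col = c("black", "red3"),
                        xlab = "% gait cycle", ylab = "deg", main = j)
    }
  } else if (which == "grf") {
    ct <- .traj_contact_cpp(model_ptr(x$model), traj$X)
    bw <- x$model$body_mass * x$model$gravity
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    graphics::matplot(ph, t(ct$grf[c(2, 4), ]) / bw, type = "l", lty = 1:2,
                      col = c("black", "red3"), xlab = "% gait cycle",
                      ylab = "vertical GRF (BW)", main = "vertical")
    graphics::matplot(ph, t(ct$grf[c(1, 3), ]) / bw, type = "l", lty = 1:2,
                      col = c("black", "red3"), xlab = "% gait cycle",
                      ylab = "horizontal GRF (BW)", main = "fore-aft")
  } else {
    graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    graphics::matplot(ph, t(traj_a(traj)[1:12, ]), type = "l",
                      xlab = "% gait cycle", ylab = "activation",
                      main = "right (non-paretic)")
    graphics::matplot(ph, t(traj_a(traj)[13:24, ]), type = "l",
                      xlab = "% gait cycle", ylab = "activation",
                      main = "left (paretic)")
  }
  invisible(x)
}
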