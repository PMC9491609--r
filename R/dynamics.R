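#' Skeletal forward dynamics
#'
#' Generalized accelerations of the 11-DOF planar skeleton given the current
#' kinematic state and the normalized tendon forces (muscle forces enter as
#' `ft * f_iso_max` through the constant moment arms; foot-ground contact
#' forces are evaluated internally from the state). All force fields are
#' smooth, so the accelerations are differentiable everywhere.
#'
#' @param model a `gait_model`.
#' @param q,u 11-vectors of coordinates and speeds.
#' @param ft 24-vector of normalized tendon forces (defaults to zero:
#'   passive ballistic motion).
#' @return 11-vector of generalized accelerations.
#' @export
skeletal_dynamics <- function(model, q, u, ft = rep(0, 24)) {
  stopifnot(length(q) == 11L, length(u) == 11L, length(ft) == 24L,
            all(is.finite(q)), all(is.finite(u)), all(is.finite(ft)))
  out <- .fwd_dyn_cpp(model_ptr(model), q, u, ft)
  if (any(!is.finite(out))) stop("invalid model definition: singular dynamics")
  out
}

#' Inverse dynamics
#'
#' Joint torques realizing prescribed accelerations; used for testing and for
#' constructing dynamically informed initial guesses.
#'
#' @inheritParams skeletal_dynamics
#' @param udot 11-vector of generalized accelerations.
#' @param contact,gravity include contact forces / gravity.
#' @return 11-vector of generalized forces.
#' @export
inverse_dynamics <- function(model, q, u, udot, contact = TRUE, gravity = TRUE) {
  .inv_dyn_cpp(model_ptr(model), q, u, udot, contact, gravity)
}

#' Foot-ground contact forces
#'
#' Smooth sphere-ground contact: a smoothed Hunt-Crossley normal force with
#' velocity-dependent dissipation and tanh-smoothed Coulomb friction. Forces
#' vanish smoothly as a sphere clears the ground and are defined for all
#' states.
#'
#' @inheritParams skeletal_dynamics
#' @return list with per-sphere horizontal/vertical forces (10 each, right
#'   foot spheres first), per-foot summed GRF (`fx_r, fy_r, fx_l, fy_l`),
#'   and the heel-sphere centre positions.
#' @export
contact_forces <- function(model, q, u = rep(0, 11)) {
  res <- .contact_cpp(model_ptr(model), q, u)
  names(res$grf) <- c("fx_r", "fy_r", "fx_l", "fy_l")
  names(res$heel_x) <- names(res$heel_y) <- c("right", "left")
  res
}

#' State derivative of the full musculoskeletal system
#'
#' Time derivative of the 70-dimensional state (11 q, 11 u, 24 activations,
#' 24 normalized tendon forces) under the 48 controls (24 excitations, 24
#' tendon-force derivatives). The tendon-force rows simply return the control
#' (implicit dynamics: the equilibrium residual constrains them separately).
#'
#' @param model a `gait_model`.
#' @param x state 70-vector; `ctrl` control 48-vector.
#' @return 70-vector dx/dt.
#' @export
state_derivative <- function(model, x, ctrl) {
  stopifnot(length(x) == 70L, length(ctrl) == 48L)
  .state_deriv_cpp(model_ptr(model), x, ctrl)
}
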