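#' Muscle characteristic curves
#'
#' The dimensionless active and passive force-length curves, force-velocity
#' multiplier, and exponential tendon force-strain curve of the Hill-type
#' muscle model. All curves are smooth (C1) everywhere, as required by
#' gradient-based trajectory optimization: the active curve is a sum of three
#' Gaussians peaking at optimal length, the force-velocity curve is a
#' logarithmic fit equal to ~1 at zero velocity, and the tendon curve is
#' exponential, crossing zero just above slack length.
#'
#' @param normalized_length fiber length / optimal fiber length.
#' @param normalized_velocity fiber velocity / (vmax * optimal length),
#'   negative when shortening.
#' @param tendon_strain_length tendon length / slack length.
#' @return list with `active_fl`, `passive_fl`, `fv`, `tendon_fl`.
#' @export
characteristic_curves <- function(normalized_length = 1,
                                  normalized_velocity = 0,
                                  tendon_strain_length = 1) {
  nl <- max(length(normalized_length), length(normalized_velocity))
  .muscle_curves_cpp(rep_len(as.numeric(normalized_length), nl),
                     rep_len(as.numeric(normalized_velocity), nl),
                     as.numeric(tendon_strain_length))
}

#' Muscle activation dynamics
#'
#' First-order excitation-to-activation dynamics with distinct activation and
#' deactivation time constants, blended smoothly (tanh) so the rate is
#' differentiable in both arguments. The rate is positive when `e > a` and
#' negative when `e < a`.
#'
#' @param e excitation in `[0.001, 1]`; `a` activation in `[0.001, 1]`.
#' @param params list with `activation_tau`, `deactivation_tau` (s); defaults
#'   to the packaged muscle constants.
#' @return da/dt (1/s), vectorized over `e` and `a`.
#' @export
activation_dynamics <- function(e, a, params = list(activation_tau = 0.015,
                                                    deactivation_tau = 0.060)) {
  n <- max(length(e), length(a))
  .act_dyn_cpp(rep_len(as.numeric(e), n), rep_len(as.numeric(a), n),
               params$activation_tau, params$deactivation_tau)
}

#' Implicit tendon equilibrium residual
#'
#' The muscle-tendon equilibrium expressed as a residual in the normalized
#' tendon force and its time derivative: the fiber state (length, velocity,
#' pennation) is recovered from the tendon stretch implied by `f_tendon_norm`,
#' and the residual is the imbalance between the fiber force (active
#' force-length x force-velocity + passive + damping, projected along the
#' tendon) and the tendon force. Zero residual defines the admissible
#' dynamics; the collocation enforces it at every node.
#'
#' @param model a `gait_model`.
#' @param muscle muscle index 1..24 (right limb 1..12, left 13..24) or name.
#' @param a activation; `f_tendon_norm` normalized tendon force;
#'   `df_tendon_norm` its time derivative (1/s).
#' @param l_mt,v_mt muscle-tendon length (m) and lengthening velocity (m/s).
#' @return dimensionless residual (vectorized over the state arguments).
#' @export
tendon_equilibrium_residual <- function(model, muscle, a, f_tendon_norm,
                                        df_tendon_norm, l_mt, v_mt) {
  if (is.character(muscle)) muscle <- match(muscle, muscle_names2(model))
  n <- max(lengths(list(a, f_tendon_norm, df_tendon_norm, l_mt, v_mt)))
  .tendon_residual_cpp(model_ptr(model), rep_len(as.integer(muscle), n),
                       rep_len(a, n), rep_len(f_tendon_norm, n),
                       rep_len(df_tendon_norm, n), rep_len(l_mt, n),
                       rep_len(v_mt, n))
}

#' Muscle-tendon lengths and velocities at a skeletal state
#'
#' Constant-moment-arm geometry: each muscle-tendon length is an affine
#' function of the joint angles it spans (`l = l_ref - sum r_j q_j`), so the
#' moment arm equals minus the length's derivative with respect to the joint
#' angle by construction.
#'
#' @param model a `gait_model`.
#' @param q,u 11-vectors of coordinates and speeds.
#' @return list with `lmt` (m) and `vmt` (m/s), length 24.
#' @export
muscle_geometry <- function(model, q, u = rep(0, 11)) {
  res <- .muscle_geometry_cpp(model_ptr(model), q, u)
  names(res$lmt) <- names(res$vmt) <- muscle_names2(model)
  res
}
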