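#' Step length and step time asymmetry indices
#'
#' Signed percent indices: `100 * (NP - P) / (NP + P)` for the non-paretic
#' (right) and paretic (left) step values. Positive values mean the
#' non-paretic value exceeds the paretic; the indices are antisymmetric under
#' a side swap and bounded in `[-100, 100]` for non-negative steps.
#'
#' @param sl_np,sl_p non-paretic and paretic step lengths (m).
#' @return signed percent asymmetry.
#' @export
sla <- function(sl_np, sl_p) {
  if (any(sl_np + sl_p == 0)) stop("step lengths sum to zero")
  100 * (sl_np - sl_p) / (sl_np + sl_p)
}

#' @rdname sla
#' @param st_np,st_p non-paretic and paretic step times (s).
#' @export
sta <- function(st_np, st_p) {
  if (any(st_np + st_p == 0)) stop("step times sum to zero")
  100 * (st_np - st_p) / (st_np + st_p)
}

#' Smooth symmetry-goal configuration
#'
#' Settings for the smooth step-length and step-time symmetry objective
#' terms. The step-length goal accumulates a softplus penalty whenever the
#' fore-aft heel-to-heel distance exceeds the target step length (half the
#' nominal condition's stride length) in either leading configuration; the
#' step-time goal is the squared smooth node-count asymmetry, with logistic
#' contact indicators on the vertical GRF and double-support nodes attributed
#' to the leading foot by a smooth fore-aft weighting. These goals are the
#' package's own smooth re-derivation of the verbal construction; they are
#' approximations, and the exact indices are always recomputed post hoc.
#'
#' @param target_stride_length stride length of the matching nominal
#'   condition (m); the target step length is half of it per side.
#' @param w_sl,w_st objective weights (defaults 8 and 5; the step-length-only
#'   experiment uses `w_st = 0`).
#' @param sharpness softplus steepness of the step-length overshoot (1/m).
#' @param contact_force_threshold vertical-force threshold (N) centring the
#'   smooth contact indicator (the foot-strike threshold).
#' @param contact_sharpness logistic steepness of the contact indicator
#'   (per threshold unit).
#' @param lead_sharpness logistic steepness of the leading-foot attribution
#'   (1/m).
#' @return a `symmetry_goal_config` list.
#' @export
symmetry_goal_config <- function(target_stride_length, w_sl = 8, w_st = 5,
                                 sharpness = 30, contact_force_threshold = 20,
                                 contact_sharpness = 4, lead_sharpness = 30) {
  stopifnot(target_stride_length > 0, w_sl >= 0, w_st >= 0, sharpness > 0)
  structure(list(target_stride_length = target_stride_length,
                 target_step_length = target_stride_length / 2,
                 w_sl = w_sl, w_st = w_st, sharpness = sharpness,
                 contact_force_threshold = contact_force_threshold,
                 contact_sharpness = contact_sharpness,
                 lead_sharpness = lead_sharpness,
                 target_step = target_stride_length / 2),
            class = "symmetry_goal_config")
}

#' Smooth step-length symmetry goal
#'
#' @param traj a `gait_trajectory`.
#' @param model a `gait_model`.
#' @param cfg a [symmetry_goal_config()].
#' @return the dimensionless penalty (zero, to smoothing tolerance, when the
#'   inter-heel distance never exceeds the target step length; positive and
#'   increasing with overshoot otherwise).
#' @export
step_length_goal <- function(traj, model, cfg) {
  .symmetry_terms_cpp(model_ptr(model), traj$X, cfg$target_step_length,
                      cfg$sharpness, cfg$contact_force_threshold,
                      cfg$contact_sharpness, cfg$lead_sharpness)$sls
}

#' Smooth step-time symmetry goal
#'
#' @inheritParams step_length_goal
#' @return squared smooth node-count asymmetry (zero for equal per-side
#'   contact node counts).
#' @export
step_time_goal <- function(traj, model, cfg) {
  .symmetry_terms_cpp(model_ptr(model), traj$X, cfg$target_step_length,
                      cfg$sharpness, cfg$contact_force_threshold,
                      cfg$contact_sharpness, cfg$lead_sharpness)$sts
}

# hard (non-smooth) oracles of the two goals, used for verification: the
# step-length overshoot integral with a sharp threshold, and the plain
# node-count asymmetry with hard contact threshold and leading-foot rule.
hard_step_length_penalty <- function(heel_x, target_step, n, tf) {
  sep <- heel_x[1, ] - heel_x[2, ]
  oR <- pmax(sep - target_step, 0)
  oL <- pmax(-sep - target_step, 0)
  w <- simpson_weights(n, 1 / (n - 1))
  sum(w * (oR^2 + oL^2)) / target_step^2
}

hard_step_time_asymmetry <- function(grf, heel_x, threshold = 20) {
  n <- ncol(grf)
  idx <- seq_len(n - 1)
  inR <- grf[2, idx] > threshold
  inL <- grf[4, idx] > threshold
  lead_r <- heel_x[1, idx] > heel_x[2, idx]
  nR <- sum(inR & (!inL | lead_r))
  nL <- sum(inL & (!inR | !lead_r))
  (nR - nL) / max(nR + nL, 1)
}
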