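# Muscle-level metabolic energetics. Two published whole-muscle models are
# implemented from their original formulations: the Umberger model
# (activation/maintenance heat + shortening/lengthening heat + positive fiber
# work, per kg muscle, with an aerobic scaling factor) and the Bhargava model
# (activation + maintenance + shortening heat + fiber work, with excitation-
# driven heat rates weighted by fiber-type fractions). Coefficients live in
# `metabolic_parameters()` so the provenance of every constant is explicit.

#' Metabolic model coefficients
#'
#' The heat-rate coefficients of the two supported muscle energetics models.
#' Fiber-type fractions are per-muscle (commonly published lower-limb values,
#' stored in the model config); muscle masses derive from peak strength,
#' optimal fiber length, specific tension, and density, and are held fixed
#' across weakness levels (weakness without atrophy).
#'
#' @return nested list of coefficients.
#' @export
metabolic_parameters <- function() {
  list(
    umberger = list(
      aerobic_scale = 1.5,          # S, steady-state aerobic conditions
      act_maint_st = 25,            # W/kg, slow-twitch activation+maintenance
      act_maint_ft = 128,           # W/kg addition at 100% fast-twitch
      maint_fraction = 0.6,         # maintenance part scaled by Fiso(l) above optimal
      vmax_st_divisor = 2.5,        # vmax(ST) = vmax(FT) / 2.5
      alpha_short_st_coef = 100,    # alpha_S(ST) = 100 / vmax(ST)
      alpha_short_ft_coef = 153,    # alpha_S(FT) = 153 / vmax(FT)
      alpha_lengthen_frac = 0.3,    # alpha_L = 0.3 * alpha_S(ST)
      negative_work = FALSE,        # positive fiber work only
      clamp_nonnegative = TRUE),
    bhargava = list(
      act_st = 40, act_ft = 133,    # W/kg activation heat rates
      maint_st = 74, maint_ft = 111,  # W/kg maintenance heat rates
      shortening_coef = 0.25,       # alpha = 0.25 * fiber force, shortening only
      negative_work = FALSE,
      clamp_nonnegative = TRUE),
    basal_rate = 1.2                # W/kg body mass, whole-body basal
  )
}

#' Metabolic configuration
#'
#' @param model_choice `"umberger"` (default) or `"bhargava"`.
#' @param include_basal add the whole-body basal rate (default TRUE).
#' @return a `metabolic_config` list.
#' @export
metabolic_config <- function(model_choice = c("umberger", "bhargava"),
                             include_basal = TRUE) {
  model_choice <- match.arg(model_choice)
  list(model_choice = model_choice, include_basal = include_basal)
}

# piecewise-linear maintenance-heat length dependence (Bhargava)
.bhargava_flen <- function(lm) {
  ifelse(lm <= 0.5, 0.5,
         ifelse(lm <= 1.0, lm,
                ifelse(lm <= 1.5, -2 * lm + 3, 0)))
}

#' Per-muscle metabolic rate along a trajectory
#'
#' @param traj a solved `gait_trajectory`.
#' @param model a `gait_model`.
#' @param cfg a [metabolic_config()].
#' @return 24 x n matrix of metabolic power (W) per muscle at the nodes
#'   (basal excluded; it is whole-body and added in [energy_report()]).
#' @export
metabolic_rate <- function(traj, model, cfg = metabolic_config()) {
  if (!cfg$model_choice %in% c("umberger", "bhargava"))
    stop("unknown metabolic model: ", cfg$model_choice)
  fl <- model_flat(model)
  fib <- .traj_fiber_cpp(model_ptr(model), traj$X, traj$C)
  a <- traj_a(traj); e <- traj_e(traj)
  n <- traj$n
  mm <- fl$mmass                      # kg, fixed across weakness levels
  ft <- fl$ftfrac
  vmax <- fl$vmax                     # lopt/s (fast-twitch maximum)
  lm <- fib$lm_tilde
  vbar <- fib$vm_tilde * vmax         # fiber velocity in lopt/s (<0 shortening)
  w_rate <- fib$fiber_power / mm      # W/kg, positive when shortening
  pars <- metabolic_parameters()
  fiso <- matrix(.muscle_curves_cpp(as.numeric(lm), numeric(length(lm)),
                                    1)$active_fl, 24, n)
  if (cfg$model_choice == "umberger") {
    p <- pars$umberger
    A <- ifelse(e > a, e, (e + a) / 2)
    A_am <- A^0.6; A_s <- A^2
    h_am0 <- (p$act_maint_ft * ft + p$act_maint_st)
    scale_l <- ifelse(lm > 1, (1 - p$maint_fraction) + p$maint_fraction * fiso, 1)
    h_am <- h_am0 * A_am * p$aerobic_scale * scale_l
    vmax_st <- vmax / p$vmax_st_divisor
    a_st <- p$alpha_short_st_coef / vmax_st
    a_ft <- p$alpha_short_ft_coef / vmax
    a_len <- p$alpha_lengthen_frac * a_st
    h_sl <- matrix(0, 24, n)
    short <- vbar <= 0
    h_sl[short] <- -((a_st * (1 - ft) + a_ft * ft)[row(vbar)[short]] *
                       vbar[short]) * A_s[short] * p$aerobic_scale
    h_sl[!short] <- (a_len[row(vbar)[!short]] * vbar[!short]) * A[!short] *
      p$aerobic_scale
    h_sl <- h_sl * ifelse(lm > 1, fiso, 1)
    w <- pmax(w_rate, 0)
    rate <- h_am + h_sl + w
    if (p$clamp_nonnegative) rate <- pmax(rate, 0)
  } else {
    p <- pars$bhargava
    u_st <- sin(pi / 2 * e); u_ft <- 1 - cos(pi / 2 * e)
    hact <- (1 - ft) * p$act_st * u_st + ft * p$act_ft * u_ft
    hmnt <- .bhargava_flen(lm) * ((1 - ft) * p$maint_st * u_st +
                                    ft * p$maint_ft * u_ft)
    # shortening heat: alpha * (-v_fiber), with v in m/s and alpha ~ force
    v_ms <- fib$vm_tilde * vmax * fl$lopt       # m/s
    hsh <- pmax(-p$shortening_coef * fib$fiber_force * v_ms, 0) / mm
    w <- pmax(w_rate, 0)
    rate <- hact + hmnt + hsh + w
    if (p$clamp_nonnegative) rate <- pmax(rate, 0)
  }
  rate * mm   # W per muscle
}

#' Positive and negative mechanical fiber work of a stride
#'
#' Fiber power per muscle is split into its positive and negative parts,
#' integrated over the stride (trapezoid on the solution grid), and summed
#' per limb; the mechanical cost of transport divides by body mass times
#' pelvis displacement.
#'
#' @param traj a solved `gait_trajectory`; `model` a `gait_model`.
#' @param power optional 24 x n matrix of fiber power (W) overriding the
#'   model-based computation (used for analytic test traces).
#' @param body_mass,displacement used for COT normalization; defaults come
#'   from the model and trajectory.
#' @return list with per-limb `w_pos`, `w_neg` (J), and
#'   `mech_cot_pos`, `mech_cot_neg` (J/kg/m).
#' @export
mechanical_work <- function(traj, model = NULL, power = NULL,
                            body_mass = NULL, displacement = NULL) {
  if (is.null(power)) {
    stopifnot(!is.null(model))
    power <- .traj_fiber_cpp(model_ptr(model), traj$X, traj$C)$fiber_power
  }
  if (is.null(body_mass)) body_mass <- if (!is.null(model)) model$body_mass else NA
  if (is.null(displacement)) displacement <- pelvis_displacement(traj)
  trapz <- function(y) sum(diff(traj$times) * (y[-length(y)] + y[-1]) / 2)
  wp <- apply(pmax(power, 0), 1, trapz)
  wn <- apply(pmin(power, 0), 1, trapz)
  right <- 1:12; left <- 13:24
  w_pos <- c(np = sum(wp[right]), p = sum(wp[left]), total = sum(wp))
  w_neg <- c(np = sum(wn[right]), p = sum(wn[left]), total = sum(wn))
  list(w_pos = w_pos, w_neg = w_neg,
       mech_cot_pos = w_pos / (body_mass * displacement),
       mech_cot_neg = w_neg / (body_mass * displacement))
}

#' Cost of transport
#'
#' @param energy total energy (J); `body_mass` kg; `displacement` m.
#' @return energy / (mass x distance), J/kg/m.
#' @export
cost_of_transport <- function(energy, body_mass, displacement) {
  if (any(displacement <= 0)) stop("displacement must be positive")
  energy / (body_mass * displacement)
}

#' Integrated muscle activation per limb
#'
#' @param traj a solved `gait_trajectory`.
#' @return named vector: non-paretic, paretic, and total summed
#'   time-integrals of activation (dimensionless x s).
#' @export
integrated_activation <- function(traj) {
  a <- traj_a(traj)
  trapz <- function(y) sum(diff(traj$times) * (y[-length(y)] + y[-1]) / 2)
  ia <- apply(a, 1, trapz)
  c(np = sum(ia[1:12]), p = sum(ia[13:24]), total = sum(ia))
}

#' Full energetic report for a solved stride
#'
#' @param traj a solved `gait_trajectory`; `model` a `gait_model`.
#' @param cfg a [metabolic_config()].
#' @return an `energy_report`: per-muscle metabolic energy, per-limb and
#'   total metabolic cost of transport, positive/negative mechanical work and
#'   COT, and integrated activation.
#' @export
energy_report <- function(traj, model, cfg = metabolic_config()) {
  rate <- metabolic_rate(traj, model, cfg)
  trapz <- function(y) sum(diff(traj$times) * (y[-length(y)] + y[-1]) / 2)
  e_mus <- apply(rate, 1, trapz)
  names(e_mus) <- muscle_names2(model)
  disp <- pelvis_displacement(traj)
  bm <- model$body_mass
  basal <- if (cfg$include_basal)
    metabolic_parameters()$basal_rate * bm * traj$tf else 0
  e_np <- sum(e_mus[1:12]); e_p <- sum(e_mus[13:24])
  total <- e_np + e_p + basal
  mw <- mechanical_work(traj, model)
  structure(list(
    model_choice = cfg$model_choice,
    per_muscle = e_mus,
    basal = basal,
    energy = c(np = e_np, p = e_p, total = total),
    cot = c(np = cost_of_transport(e_np + basal / 2, bm, disp),
            p = cost_of_transport(e_p + basal / 2, bm, disp),
            total = cost_of_transport(total, bm, disp)),
    w_pos = mw$w_pos, w_neg = mw$w_neg,
    mech_cot_pos = mw$mech_cot_pos, mech_cot_neg = mw$mech_cot_neg,
    integrated_activation = integrated_activation(traj),
    displacement = disp, body_mass = bm, stride_time = traj$tf),
    class = "energy_report")
}

#' @method print energy_report
#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("energetics (%s model): COT %.3f J/kg/m (NP %.3f, P %.3f)\n",
              x$model_choice, x$cot["total"], x$cot["np"], x$cot["p"]))
  cat(sprintf("  mechanical COT +%.3f / %.3f J/kg/m; integrated activation %.3f\n",
              x$mech_cot_pos["total"], x$mech_cot_neg["total"],
              x$integrated_activation["total"]))
  invisible(x)
}

#' @method as.data.frame energy_report
#' @export
as.data.frame.energy_report <- function(x, ...) {
  limb <- c("np", "p", "total")
  data.frame(limb = limb,
             metabolic_cot = as.numeric(x$cot[limb]),
             w_pos = as.numeric(x$w_pos[limb]),
             w_neg = as.numeric(x$w_neg[limb]),
             mech_cot_pos = as.numeric(x$mech_cot_pos[limb]),
             mech_cot_neg = as.numeric(x$mech_cot_neg[limb]),
             integrated_activation = as.numeric(x$integrated_activation[limb]),
             model_choice = x$model_choice)
}
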