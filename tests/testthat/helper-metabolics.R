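# independent loop-based transcription of the two energetics models, coded
# directly from the documented equations (oracle for the vectorized
# implementation)
oracle_rates <- function(traj, model, choice) {
  fl <- hemigait:::model_flat(model)
  fib <- hemigait:::.traj_fiber_cpp(hemigait:::model_ptr(model), traj$X, traj$C)
  pars <- metabolic_parameters()
  n <- traj$n
  out <- matrix(0, 24, n)
  for (m in 1:24) {
    for (k in 1:n) {
      a <- traj$X[22 + m, k]; e <- traj$C[m, k]
      ft <- fl$ftfrac[m]; vmax <- fl$vmax[m]
      lm <- fib$lm_tilde[m, k]
      vbar <- fib$vm_tilde[m, k] * vmax
      fiso <- hemigait:::.muscle_curves_cpp(lm, 0, 1)$active_fl
      w_rate <- max(fib$fiber_power[m, k] / fl$mmass[m], 0)
      if (choice == "umberger") {
        p <- pars$umberger
        A <- if (e > a) e else (e + a) / 2
        h_am <- (p$act_maint_ft * ft + p$act_maint_st) * A^0.6 * p$aerobic_scale
        if (lm > 1) h_am <- h_am * ((1 - p$maint_fraction) +
                                      p$maint_fraction * fiso)
        vmax_st <- vmax / p$vmax_st_divisor
        a_st <- p$alpha_short_st_coef / vmax_st
        a_ft <- p$alpha_short_ft_coef / vmax
        if (vbar <= 0) {
          h_sl <- -(a_st * (1 - ft) + a_ft * ft) * vbar * A^2 * p$aerobic_scale
        } else {
          h_sl <- p$alpha_lengthen_frac * a_st * vbar * A * p$aerobic_scale
        }
        if (lm > 1) h_sl <- h_sl * fiso
        r <- max(h_am + h_sl + w_rate, 0)
      } else {
        p <- pars$bhargava
        u_st <- sin(pi / 2 * e); u_ft <- 1 - cos(pi / 2 * e)
        hact <- (1 - ft) * p$act_st * u_st + ft * p$act_ft * u_ft
        L <- if (lm <= 0.5) 0.5 else if (lm <= 1) lm else if (lm <= 1.5) 3 - 2 * lm else 0
        hmnt <- L * ((1 - ft) * p$maint_st * u_st + ft * p$maint_ft * u_ft)
        v_ms <- fib$vm_tilde[m, k] * vmax * fl$lopt[m]
        hsh <- max(-p$shortening_coef * fib$fiber_force[m, k] * v_ms, 0) / fl$mmass[m]
        r <- max(hact + hmnt + hsh + w_rate, 0)
      }
      out[m, k] <- r * fl$mmass[m]
    }
  }
  out
}

random_muscle_traj <- function(n = 25L, seed = 9) {
  set.seed(seed)
  q <- matrix(0, 11, n)
  q[1, ] <- seq(0, 1, length.out = n); q[2, ] <- 0.94
  q[4:11, ] <- runif(8 * n, -0.3, 0.3)
  u <- matrix(runif(11 * n, -1, 1), 11, n)
  a <- matrix(runif(24 * n, 0.001, 1), 24, n)
  ft <- matrix(runif(24 * n, 0, 1.2), 24, n)
  e <- matrix(runif(24 * n, 0.001, 1), 24, n)
  dft <- matrix(runif(24 * n, -20, 20), 24, n)
  gait_trajectory(1, q, u, a, ft, e, dft)
}

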