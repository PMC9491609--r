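# Surrogate normative reference gait. Real tracking references (averaged
# treadmill kinematics + GRFs) are not shipped; this generator emulates their
# structure: smooth periodic joint-angle curves within physiological ranges,
# double-peaked vertical GRFs whose cycle average equals body weight, and
# per-channel SDs of published order of magnitude. Phase 0 is right (non-
# paretic) heel strike; the left leg is the right's curves shifted by half a
# cycle.

# The joint-angle curves are constructed in task space and converted by leg
# inverse kinematics: each foot is flat on the ground through stance (62% of
# the cycle, heel rising over the metatarsal pivot in late stance with the
# toes kept flat), swings forward along a cycloid with a clearance bell, and
# the pelvis rides the compass-gait arc implied by leg reach. This guarantees
# grounded, correctly timed foot contact. The piecewise-smooth curves are
# projected on a truncated Fourier basis so the stored speeds are exact time
# derivatives of the angles.

.duty <- 0.62          # stance fraction per foot (incl. double support)

# value(phase) = a0 + sum Ak cos(2 pi k (phase - pk)); exact derivative
.fourier_eval <- function(cf, phase, deriv = FALSE, period = 1) {
  out <- if (deriv) numeric(length(phase)) else rep(cf$a0, length(phase))
  for (i in seq_along(cf$A)) {
    w <- 2 * pi * cf$k[i]
    if (deriv)
      out <- out - cf$A[i] * w / period * sin(w * (phase - cf$p[i]))
    else
      out <- out + cf$A[i] * cos(w * (phase - cf$p[i]))
  }
  out
}

# periodic least-squares Fourier fit in the same amplitude/phase form
.fourier_fit <- function(phase, y, harmonics = 12) {
  X <- cbind(1, do.call(cbind, lapply(seq_len(harmonics), function(k)
    cbind(cos(2 * pi * k * phase), sin(2 * pi * k * phase)))))
  b <- stats::lm.fit(X, y)$coefficients
  A <- p <- numeric(harmonics)
  for (k in seq_len(harmonics)) {
    ck <- b[2 * k]; sk <- b[2 * k + 1]
    A[k] <- sqrt(ck^2 + sk^2)
    p[k] <- atan2(sk, ck) / (2 * pi * k)
  }
  list(a0 = unname(b[1]), A = A, k = seq_len(harmonics), p = p)
}

# single-foot vertical GRF shape over stance fraction s in [0,1]
.grf_shape <- function(s) sin(pi * s) + 0.3 * sin(3 * pi * s)


# smooth C1 ramp 0 -> 1 on [0, 1]
.smooth01 <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# ankle-point position and foot pitch over one cycle (phase of THIS foot,
# strike at 0); returns world x (for anchor at 0), y, foot pitch, toe angle
.foot_task <- function(ph, L, h0, geom) {
  mtp_x <- geom$mtp[1]; mtp_y <- geom$mtp[2]
  lift <- geom$step_clearance
  heel_rise <- 0.40    # heel-rise begins at this fraction of the cycle
  th_max <- geom$heel_rise_angle
  pen <- geom$penetration
  n <- length(ph)
  x <- y <- thf <- numeric(n)
  for (i in seq_len(n)) {
    p <- ph[i] %% 1
    if (p <= .duty) {
      # stance: ankle anchored horizontally; the foot touches down with zero
      # force and sinks to its working penetration over the first 10% of the
      # cycle (a smooth, physiological loading ramp), then the heel rises
      # about the metatarsal joint in late stance
      h_eff <- h0 + pen * (1 - .smooth01(p / 0.10))
      r <- .smooth01((p - heel_rise) / (.duty - heel_rise))
      th <- -th_max * r
      # friction-consistent creep: the smoothed Coulomb law produces fore-aft
      # force only with a small sliding velocity, so the stance foot creeps
      # forward under braking and back under propulsion (sub-millimetre)
      sst <- p / .duty
      creep <- geom$creep_gain * (1 - cos(2 * pi * sst)) / (2 * pi)
      cx <- mtp_x + creep; cy <- h_eff + mtp_y
      ax <- cx + cos(th) * (-mtp_x) - sin(th) * (-mtp_y)
      ay <- cy + sin(th) * (-mtp_x) + cos(th) * (-mtp_y)
      x[i] <- ax; y[i] <- ay; thf[i] <- th
    } else {
      s <- (p - .duty) / (1 - .duty)
      # start point: ankle pose at end of stance (full heel rise)
      th0 <- -th_max
      ax0 <- mtp_x + cos(th0) * (-mtp_x) - sin(th0) * (-mtp_y)
      ay0 <- h0 + mtp_y + sin(th0) * (-mtp_x) + cos(th0) * (-mtp_y)
      adv <- s - sin(2 * pi * s) / (2 * pi)     # cycloid: zero end velocities
      x[i] <- ax0 + (L - ax0) * adv
      y[i] <- (h0 + pen) + (ay0 - h0 - pen) * (1 - .smooth01(2 * s)) +
        lift * 0.5 * (1 - cos(2 * pi * s))
      thf[i] <- th0 * (1 - .smooth01(1.6 * s))
    }
  }
  list(x = x, y = y, pitch = thf, toe = -thf)
}

# planar two-link inverse kinematics: hip and ankle points -> joint angles
.leg_ik <- function(hx, hy, ax, ay, L1, L2) {
  dx <- ax - hx; dy <- ay - hy
  D <- pmin(sqrt(dx^2 + dy^2), 0.995 * (L1 + L2))
  gamma <- atan2(dx, -dy)                      # leg line angle, forward +
  alpha <- acos(pmin(pmax((L1^2 + D^2 - L2^2) / (2 * L1 * D), -1), 1))
  th_t <- gamma + alpha                        # thigh world angle (knee fwd)
  beta <- acos(pmin(pmax((L1^2 + L2^2 - D^2) / (2 * L1 * L2), -1), 1))
  knee <- pi - beta                            # flexion positive
  th_s <- th_t - knee
  list(thigh = th_t, knee = knee, shank = th_s)
}

#' Generate a surrogate normative reference gait
#'
#' Produces time-normalized (101-sample) means and standard deviations for the
#' 11 coordinates, 11 speeds, and 4 ground-reaction-force channels of one
#' stride. The curves are built in task space (grounded stance with a late
#' heel rise, cycloidal swing, compass-gait pelvis arc) and converted by leg
#' inverse kinematics, so the stance foot is on the ground at the right times
#' by construction; a truncated Fourier projection makes every channel
#' periodic with speeds that are exact time derivatives of the angles. By
#' default the construction adapts to the target speed; `fixed_shape = TRUE`
#' reuses the nominal (1.4 m/s) shape across speeds instead. Per-limb
#' vertical GRFs are double-peaked and average body weight over the cycle.
#'
#' @param speed target gait speed, m/s (0.25 to 1.5).
#' @param model optional `gait_model`: when supplied, leg lengths, ankle
#'   height, metatarsal location, body mass, gravity, and the friction
#'   parameters are taken from the model so the constructed stride matches
#'   its geometry.
#' @param body_mass model mass, kg (used to scale GRFs).
#' @param gravity m/s^2.
#' @param seed integer seed; only used when `jitter > 0`.
#' @param jitter relative amplitude of smooth random perturbations added to
#'   the joint curves (default 0: fully deterministic).
#' @param fixed_shape reuse the nominal (1.4 m/s) curve shape across target
#'   speeds instead of the default speed-matched construction.
#' @param n_samples samples per cycle (101, first == last).
#' @param phase_origin where in the construction cycle (right strike at 0)
#'   the stored cycle begins; the default 0.30 starts it at right mid-stance
#'   so the periodic endpoints sit in a smooth part of the stride, away from
#'   any contact transient.
#' @return an object of class `reference_gait`.
#' @export
generate_reference <- function(speed, model = NULL, body_mass = 75.01,
                               gravity = 9.80665, seed = NULL, jitter = 0,
                               fixed_shape = FALSE, n_samples = 101L,
                               phase_origin = 0.30) {
  if (!is.numeric(speed) || speed < 0.25 || speed > 1.5)
    stop("`speed` must be between 0.25 and 1.5 m/s")
  if (!is.null(model)) {
    body_mass <- model$body_mass
    gravity <- model$gravity
  }
  if (jitter > 0 && is.null(seed)) stop("`seed` is required when jitter > 0")
  stride_time <- min(max(1.05 * (1.4 / speed)^0.45, 0.55), 1.9)
  shape_speed <- if (fixed_shape) 1.4 else speed
  L <- shape_speed * min(max(1.05 * (1.4 / shape_speed)^0.45, 0.55), 1.9)
  # model geometry (defaults match the packaged walker)
  geom <- list(L1 = 0.43, L2 = 0.43, ankle_h = 0.085, mtp = c(0.160, -0.045),
               step_clearance = 0.045, heel_rise_angle = 0.45)
  if (!is.null(model)) {
    geom$L1 <- model$segments$thigh$length
    geom$L2 <- model$segments$shank$length
    sph <- model$contact$spheres
    geom$ankle_h <- max(vapply(sph[1:4], function(s)
      s$radius - s$location[2], numeric(1)))
    geom$mtp <- model$mtp_location
  }
  pen <- 0.006                      # nominal stance working penetration
  h0 <- geom$ankle_h - pen
  geom$penetration <- pen
  # creep amplitude from the GRF shape, friction coefficient, and the
  # friction velocity smoothing (see .foot_task)
  vt <- 0.02; mu_f <- 0.8
  if (!is.null(model)) {
    vt <- model$contact$velocity_smoothing
    mu_f <- model$contact$friction
  }
  geom$creep_gain <- 0.163 * vt * (.duty * stride_time)
  # dense construction grid, then Fourier projection (exact derivatives)
  nd <- 480L
  phd <- seq(0, 1, length.out = nd + 1L)[-(nd + 1L)]
  # pelvis path: forward at the target speed; vertical on the compass arc
  reach <- 0.99 * (geom$L1 + geom$L2)
  dx_strike <- 0.30 * L
  y_mid <- h0 + reach * 0.995
  y_ds <- h0 + sqrt(max(reach^2 - dx_strike^2, 0.01))
  ybar <- (y_mid + y_ds) / 2
  yamp <- (y_mid - y_ds) / 2
  mid_stance <- .duty / 2
  hip_x <- shape_speed * stride_time * phd - dx_strike
  hip_y <- ybar + yamp * cos(4 * pi * (phd - mid_stance))
  tilt <- rep(8 * pi / 180, nd)   # constant forward tilt
  qd <- matrix(0, 11, nd, dimnames = list(coordinate_names, NULL))
  qd["pelvis_ty", ] <- hip_y
  qd["pelvis_tilt", ] <- tilt
  for (side in c("r", "l")) {
    shift <- if (side == "r") 0 else 0.5
    pf <- (phd - shift) %% 1
    ft <- .foot_task(pf, L, h0, geom)
    # world anchor: the foot strikes at its own phase 0 with the ankle a
    # strike-distance ahead of the hip at that instant
    x_anchor <- shape_speed * stride_time * shift +
      ft$x + floor(phd - shift + 1) * L - L
    ik <- .leg_ik(hip_x, hip_y, x_anchor, ft$y, geom$L1, geom$L2)
    qd[paste0("hip_", side), ] <- ik$thigh - tilt
    qd[paste0("knee_", side), ] <- ik$knee
    qd[paste0("ankle_", side), ] <- ft$pitch - ik$shank
    qd[paste0("toe_", side), ] <- ft$toe
  }
  # Fourier projection of every channel; speeds are analytic derivatives
  ph <- seq(0, 1, length.out = n_samples)
  q <- matrix(0, 11, n_samples, dimnames = list(coordinate_names, NULL))
  u <- matrix(0, 11, n_samples, dimnames = list(coordinate_names, NULL))
  q["pelvis_tx", ] <- speed * stride_time * ph
  u["pelvis_tx", ] <- speed
  for (nm in coordinate_names[-1]) {
    fit <- .fourier_fit(phd, qd[nm, ], harmonics = 12)
    jit_q <- 0; jit_u <- 0
    if (jitter > 0) {
      set.seed(seed + match(nm, coordinate_names))
      aj <- stats::rnorm(2, 0, jitter)
      jit_q <- aj[1] * cos(2 * pi * ph) + aj[2] * sin(2 * pi * ph)
      jit_u <- 2 * pi / stride_time *
        (-aj[1] * sin(2 * pi * ph) + aj[2] * cos(2 * pi * ph))
    }
    q[nm, ] <- .fourier_eval(fit, ph + phase_origin) + jit_q
    u[nm, ] <- .fourier_eval(fit, ph + phase_origin, deriv = TRUE,
                             period = stride_time) + jit_u
  }
  q[, n_samples] <- q[, 1]; q["pelvis_tx", n_samples] <- speed * stride_time
  u[, n_samples] <- u[, 1]
  bw <- body_mass * gravity
  # double-peaked per-limb vertical GRF; cycle-average total is body weight
  alpha <- 1 / (2 * .duty * (2 / pi) * 1.1)
  grf <- matrix(0, 4, n_samples,
                dimnames = list(c("fx_r", "fy_r", "fx_l", "fy_l"), NULL))
  for (side in c("r", "l")) {
    shift <- if (side == "r") 0 else 0.5
    sst <- ((ph + phase_origin - shift) %% 1) / .duty
    inside <- sst <= 1
    grf[paste0("fy_", side), ] <-
      ifelse(inside, alpha * bw * .grf_shape(pmin(sst, 1)), 0)
    grf[paste0("fx_", side), ] <-
      ifelse(inside, -0.16 * bw * sin(2 * pi * pmin(sst, 1)), 0)
  }
  grf[, n_samples] <- grf[, 1]
  d <- pi / 180
  sd_q <- c(pelvis_tx = 0.02, pelvis_ty = 0.012, pelvis_tilt = 2 * d,
            stats::setNames(rep(4 * d, 8), coordinate_names[4:11]))
  sd_u <- sd_q * 2 * pi / stride_time
  sd_grf <- c(fx_r = 0.03 * bw, fy_r = 0.08 * bw,
              fx_l = 0.03 * bw, fy_l = 0.08 * bw)
  structure(list(n_samples = n_samples, phase = ph, q = q, u = u, grf = grf,
                 sd_q = sd_q, sd_u = sd_u, sd_grf = sd_grf,
                 speed = speed, stride_time = stride_time,
                 body_mass = body_mass, gravity = gravity),
            class = "reference_gait")
}

#' @method print reference_gait
#' @export
print.reference_gait <- function(x, ...) {
  cat(sprintf(paste0("reference gait: %d samples/cycle, speed %.2f m/s,",
                     " stride time %.3f s\n"), x$n_samples, x$speed, x$stride_time))
  invisible(x)
}

# cubic interpolation of all channels at arbitrary phases (periodic)
reference_at_phases <- function(ref, phases) {
  interp <- function(M) {
    t(apply(M, 1, function(y)
      spline(ref$phase, y, xout = phases, method = "periodic")$y))
  }
  qper <- ref$q
  qper[1, ] <- 0  # forward travel is linear, not periodic; rebuilt below
  q <- interp(qper)
  q[1, ] <- ref$speed * phases * ref$stride_time
  list(q = q, u = interp(ref$u), grf = interp(ref$grf))
}

#' Write / read a reference gait as columnar text
#'
#' 101 rows; one mean column and one SD column per channel. The same format
#' is accepted for user-supplied experimental references.
#'
#' @param ref a `reference_gait`.
#' @param file path.
#' @export
write_reference <- function(ref, file) {
  df <- data.frame(phase = ref$phase, t(ref$q), t(ref$u), t(ref$grf))
  names(df) <- c("phase", paste0("q.", coordinate_names),
                 paste0("u.", coordinate_names), rownames(ref$grf))
  for (i in seq_along(ref$sd_q)) df[[paste0("sd_q.", coordinate_names[i])]] <- ref$sd_q[i]
  for (i in seq_along(ref$sd_u)) df[[paste0("sd_u.", coordinate_names[i])]] <- ref$sd_u[i]
  for (i in seq_len(4)) df[[paste0("sd_", rownames(ref$grf)[i])]] <- ref$sd_grf[i]
  df$speed <- ref$speed; df$stride_time <- ref$stride_time
  df$body_mass <- ref$body_mass; df$gravity <- ref$gravity
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_reference
#' @export
read_reference <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  n <- nrow(df)
  getm <- function(prefix, names) {
    M <- t(as.matrix(df[paste0(prefix, names)]))
    rownames(M) <- names
    M
  }
  grf_names <- c("fx_r", "fy_r", "fx_l", "fy_l")
  structure(list(
    n_samples = n, phase = df$phase,
    q = getm("q.", coordinate_names), u = getm("u.", coordinate_names),
    grf = getm("", grf_names),
    sd_q = stats::setNames(as.numeric(df[1, paste0("sd_q.", coordinate_names)]),
                           coordinate_names),
    sd_u = stats::setNames(as.numeric(df[1, paste0("sd_u.", coordinate_names)]),
                           coordinate_names),
    sd_grf = stats::setNames(as.numeric(df[1, paste0("sd_", grf_names)]), grf_names),
    speed = df$speed[1], stride_time = df$stride_time[1],
    body_mass = df$body_mass[1], gravity = df$gravity[1]),
    class = "reference_gait")
}

#' Construct analytic test-fixture trajectories
#'
#' Fully populated trajectories (plus auxiliary heel-position and GRF tracks)
#' with known step lengths, step times, contact intervals, and power
#' profiles, for unit-testing the gait metrics, symmetry goals, and
#' energetics. Kinds:
#' \describe{
#'   \item{symmetric_gait}{mirror-symmetric heel tracks and square-ish GRF
#'     bursts; step metrics are exactly symmetric.}
#'   \item{offset_steps}{heel tracks built so the measured step lengths equal
#'     `params$sl_np` and `params$sl_p`, and step times `params$st_np`,
#'     `params$st_p`.}
#'   \item{custom_contact_pattern}{per-node contact indicator with
#'     `params$n_right` / `params$n_left` nodes in contact (of `n - 1`
#'     counted nodes).}
#' }
#'
#' @param kind fixture kind (see Details).
#' @param params list of fixture parameters; `n` nodes (odd), `tf` stride
#'   time, plus kind-specific entries.
#' @param seed seed for any randomized fill-in channels (activations).
#' @return list with `traj` (a `gait_trajectory`), `heel_x` (2 x n), `grf`
#'   (4 x n), and the analytically known metrics.
#' @export
generate_fixture_trajectory <- function(kind = c("symmetric_gait", "offset_steps",
                                                 "custom_contact_pattern"),
                                        params = list(), seed = 1) {
  kind <- match.arg(kind)
  p <- modifyList(list(n = 101L, tf = 1.0, speed = 1.2, bw = 735.6), params)
  n <- p$n; tf <- p$tf
  ph <- seq(0, 1, length.out = n)
  set.seed(seed)
  mktraj <- function(q) {
    u <- rbind(matrix(0, 11, n))
    u[1, ] <- p$speed
    a <- matrix(stats::runif(24, 0.01, 0.2), 24, n)
    gait_trajectory(tf, q, u, a, ft = a, e = a, dft = matrix(0, 24, n))
  }
  qbase <- matrix(0, 11, n); qbase[1, ] <- p$speed * ph * tf; qbase[2, ] <- 0.94
  if (kind == "custom_contact_pattern") {
    stopifnot(!is.null(p$n_right), !is.null(p$n_left))
    grf <- matrix(0, 4, n)
    # contact blocks starting at node 1 (right) and at the first node after
    # right contact ends (left); counted nodes are 1..n-1 (periodic wrap)
    ir <- seq_len(p$n_right)
    il <- ((p$n_right + seq_len(p$n_left) - 1L) %% (n - 1L)) + 1L
    grf[2, ir] <- p$bw; grf[4, il] <- p$bw
    grf[, n] <- grf[, 1]
    hx <- rbind(qbase[1, ] + 0.1, qbase[1, ] - 0.1)
    return(list(traj = mktraj(qbase), heel_x = hx, grf = grf,
                n_right = p$n_right, n_left = p$n_left))
  }
  if (kind == "symmetric_gait") {
    sl <- if (is.null(p$step_length)) 0.6 else p$step_length
    res <- .heel_tracks(ph, tf, p$speed, sl, sl, p$bw)
    return(c(list(traj = mktraj(qbase), sla = 0, sta = 0,
                  sl_np = sl, sl_p = sl), res))
  }
  # offset_steps
  stopifnot(!is.null(p$sl_np), !is.null(p$sl_p))
  st_np <- if (is.null(p$st_np)) tf / 2 else p$st_np
  # left (paretic) strike is st_np before the right strike at the wrap
  res <- .heel_tracks(ph, tf, p$speed, p$sl_np, p$sl_p, p$bw, 1 - st_np / tf)
  sla <- 100 * (p$sl_np - p$sl_p) / (p$sl_np + p$sl_p)
  st_p <- tf - st_np
  sta <- 100 * (st_np - st_p) / (st_np + st_p)
  c(list(traj = mktraj(qbase), sla = sla, sta = sta,
         sl_np = p$sl_np, sl_p = p$sl_p, st_np = st_np, st_p = st_p), res)
}

# heel tracks and GRF bursts with exact step lengths/times. Right (non-
# paretic) strike at phase 0; left strike at phase_l = st_np / tf (the
# non-paretic step time runs from left strike to right strike at the wrap).
.heel_tracks <- function(ph, tf, speed, sl_np, sl_p, bw, phase_l = 0.5) {
  n <- length(ph)
  stride <- speed * tf
  # each heel advances by one stride per cycle in a smooth step (plateau at
  # strike, rapid swing advance); plateau width 0.55 of the cycle
  plateau <- function(x) {   # 0 at x=0, 1 at x=1, flat near both ends
    s <- pmin(pmax((x - 0.60) / 0.35, 0), 1)
    s * s * (3 - 2 * s)
  }
  # right heel position at its strike (phase 0): ahead of left heel by sl_np
  # left heel at its strike (phase_l): ahead of right by sl_p
  xr <- function(p_) stride * (floor(p_) + plateau(p_ %% 1))
  xl0 <- -sl_np
  xl <- function(p_) xl0 + stride * (floor(p_ - phase_l + 1) +
                                       plateau((p_ - phase_l) %% 1))
  # nudge the left track with a smooth bump (zero away from phase_l, slope
  # zero at its peak) so that at the left strike the left heel leads by sl_p
  corr <- (xr(phase_l) + sl_p) - xl(phase_l)
  xlf <- function(p_) xl(p_) + corr * plateau2(p_, phase_l)
  hx <- rbind(xr(ph), xlf(ph))
  grf <- matrix(0, 4, n)
  stance <- 0.58
  sr <- (ph %% 1) / stance
  sl_ <- ((ph - phase_l) %% 1) / stance
  grf[2, ] <- ifelse(sr <= 1, bw * 1.1 * sin(pi * pmin(sr, 1))^0.5, 0)
  grf[4, ] <- ifelse(sl_ <= 1, bw * 1.1 * sin(pi * pmin(sl_, 1))^0.5, 0)
  grf[, n] <- grf[, 1]
  list(heel_x = hx, grf = grf)
}

# smooth periodic bump equal to 1 at phase target, 0 at phase 0/1, used to
# nudge the left heel track without moving its strike-instant positions
plateau2 <- function(p_, target) {
  x <- (p_ %% 1)
  b <- exp(-0.5 * ((x - target) / 0.10)^2)
  b
}
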