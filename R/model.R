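#' Load the sagittal-plane musculoskeletal model
#'
#' Reads a model configuration (YAML) describing segments, the 11 generalized
#' coordinates, foot contact spheres, and the 24 muscle-tendon units, and
#' returns a validated `gait_model` object. The packaged default
#' (`planar_walker.yaml`) is a standard adult parameter set (~75 kg, ~1.75 m)
#' with the published peak isometric strengths for the 12 muscles of each limb.
#'
#' @param config path to a YAML model configuration; defaults to the packaged
#'   planar walker.
#' @return an object of class `gait_model`.
#' @export
load_gait_model <- function(config = NULL) {
  if (is.null(config)) {
    config <- system.file("extdata", "planar_walker.yaml", package = "hemigait")
  }
  cfg <- yaml::read_yaml(config)
  model <- build_gait_model(cfg)
  model$source <- config
  model
}

#' @rdname load_gait_model
#' @export
default_model <- function() load_gait_model()

coordinate_names <- c("pelvis_tx", "pelvis_ty", "pelvis_tilt",
                      "hip_r", "knee_r", "ankle_r", "toe_r",
                      "hip_l", "knee_l", "ankle_l", "toe_l")

# map joint coordinate name -> column for each side's muscles
.joint_cols <- list(right = c(hip = 4L, knee = 5L, ankle = 6L, toe = 7L),
                    left  = c(hip = 8L, knee = 9L, ankle = 10L, toe = 11L))

build_gait_model <- function(cfg) {
  seg <- cfg$segments
  stopifnot(!is.null(seg$hat), !is.null(seg$thigh), !is.null(seg$shank),
            !is.null(seg$foot), !is.null(seg$toes))
  for (s in seg) {
    if (s$mass < 0 || s$inertia_zz < 0 || s$length <= 0)
      stop("segment parameters must be positive")
  }
  co <- cfg$coordinates
  if (!identical(names(co), coordinate_names))
    stop("configuration must define exactly the 11 coordinates in order: ",
         paste(coordinate_names, collapse = ", "))
  bounds <- t(vapply(co, function(x) as.numeric(x), numeric(4)))
  colnames(bounds) <- c("lower", "upper", "speed_lower", "speed_upper")
  if (any(bounds[, "lower"] >= bounds[, "upper"]))
    stop("coordinate lower bounds must be below upper bounds")

  sph <- cfg$contact$spheres
  if (length(sph) != 5L) stop("exactly 5 contact spheres per foot are required")
  for (s in sph) if (s$radius <= 0) stop("sphere radius must be positive")
  if (!isTRUE(sph[[1]]$heel)) stop("the first sphere must be the heel marker")

  mus <- cfg$muscles
  if (length(mus) != 12L) stop("exactly 12 muscles per limb are required")
  md <- cfg$muscle_defaults
  muscles <- lapply(names(mus), function(nm) {
    m <- mus[[nm]]
    if (m$f_iso_max <= 0) stop("f_iso_max must be positive for ", nm)
    list(name = nm,
         f_iso_max = m$f_iso_max,
         optimal_fiber_length = m$optimal_fiber_length,
         tendon_slack_length = m$tendon_slack_length,
         pennation_at_optimal = m$pennation_at_optimal,
         max_contraction_velocity = md$max_contraction_velocity,
         activation_tau = md$activation_tau,
         deactivation_tau = md$deactivation_tau,
         fiber_damping = md$fiber_damping,
         fast_twitch_fraction = m$fast_twitch_fraction,
         moment_arms = m$moment_arms,
         # muscle mass from base strength; held fixed under weakness scaling
         muscle_mass = md$density * m$f_iso_max * m$optimal_fiber_length /
           md$specific_tension)
  })
  names(muscles) <- names(mus)

  model <- structure(list(
    segments = seg,
    mtp_location = as.numeric(cfg$mtp_location),
    coordinates = bounds,
    contact = cfg$contact,
    passive = cfg$passive,
    calibration_pose = cfg$calibration_pose,
    muscles = muscles,
    gravity = cfg$gravity,
    weakness = c(left = 0, right = 0),
    cache = new.env(parent = emptyenv())
  ), class = "gait_model")
  model$body_mass <- with(seg, hat$mass + 2 * (thigh$mass + shank$mass +
                                                 foot$mass + toes$mass))
  model
}

#' Apply unilateral muscle weakness
#'
#' Scales the peak isometric strength of all 12 muscles on one limb by
#' `(1 - fraction)`, modelling hemiparesis without atrophy: muscle masses and
#' all other parameters are unchanged.
#'
#' @param model a `gait_model`.
#' @param fraction fractional strength reduction in `[0, 1)`.
#' @param side which limb to weaken (the paretic side); default `"left"`.
#' @return a new `gait_model` with scaled strengths.
#' @export
apply_weakness <- function(model, fraction, side = c("left", "right")) {
  stopifnot(inherits(model, "gait_model"))
  side <- match.arg(side)
  if (!is.numeric(fraction) || length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction >= 1)
    stop("`fraction` must be a single value in [0, 1)")
  out <- model
  out$cache <- new.env(parent = emptyenv())
  out$weakness[side] <- fraction
  out
}

#' Peak isometric strengths of a model
#'
#' @param model a `gait_model`.
#' @return data frame of per-muscle strengths (N) for both limbs, with any
#'   weakness scaling applied.
#' @export
muscle_strengths <- function(model) {
  base <- vapply(model$muscles, `[[`, numeric(1), "f_iso_max")
  data.frame(muscle = names(model$muscles),
             right = base * (1 - model$weakness[["right"]]),
             left = base * (1 - model$weakness[["left"]]),
             row.names = NULL)
}

#' @method print gait_model
#' @export
print.gait_model <- function(x, ...) {
  cat("Sagittal-plane gait model: 11 coordinates, 24 muscle-tendon units\n")
  cat(sprintf("  body mass %.2f kg, gravity %.4f m/s^2\n", x$body_mass, x$gravity))
  w <- x$weakness
  if (any(w > 0)) {
    side <- names(w)[w > 0]
    cat(sprintf("  unilateral weakness: %s limb -%.0f%%\n", side, 100 * w[side]))
  } else {
    cat("  symmetric strength (base model)\n")
  }
  invisible(x)
}

# flat numeric description consumed by the compiled core; body indices follow
# the coordinate order (two massless carrier bodies for the pelvis
# translations, then the HAT body, then thigh/shank/foot/toes per leg)
model_flat <- function(model) {
  seg <- model$segments
  zero2 <- c(0, 0)
  bodies <- list(
    list(m = 0, com = zero2, I = 0),                             # tx carrier
    list(m = 0, com = zero2, I = 0),                             # ty carrier
    list(m = seg$hat$mass, com = seg$hat$com, I = seg$hat$inertia_zz),
    list(m = seg$thigh$mass, com = seg$thigh$com, I = seg$thigh$inertia_zz),
    list(m = seg$shank$mass, com = seg$shank$com, I = seg$shank$inertia_zz),
    list(m = seg$foot$mass, com = seg$foot$com, I = seg$foot$inertia_zz),
    list(m = seg$toes$mass, com = seg$toes$com, I = seg$toes$inertia_zz),
    list(m = seg$thigh$mass, com = seg$thigh$com, I = seg$thigh$inertia_zz),
    list(m = seg$shank$mass, com = seg$shank$com, I = seg$shank$inertia_zz),
    list(m = seg$foot$mass, com = seg$foot$com, I = seg$foot$inertia_zz),
    list(m = seg$toes$mass, com = seg$toes$com, I = seg$toes$inertia_zz))
  lth <- seg$thigh$length
  lsh <- seg$shank$length
  mtp <- model$mtp_location
  anchors <- list(zero2, zero2, zero2,
                  zero2, c(0, -lth), c(0, -lsh), mtp,
                  zero2, c(0, -lth), c(0, -lsh), mtp)
  parent <- c(-1L, 0L, 1L, 2L, 3L, 4L, 5L, 2L, 7L, 8L, 9L)
  jtype <- c(0L, 0L, rep(1L, 9))
  axis_x <- c(1, 0, rep(0, 9))
  axis_y <- c(0, 1, rep(0, 9))
  # flexion-positive hips/toes and dorsiflexion-positive ankles rotate +z;
  # flexion-positive knees rotate -z
  axis_sign <- c(0, 0, 1, 1, -1, 1, 1, 1, -1, 1, 1)

  sph <- model$contact$spheres
  sph_body <- integer(10); sph_x <- sph_y <- sph_r <- numeric(10)
  for (i in seq_len(5)) {
    b <- if (identical(sph[[i]]$segment, "toes")) 1L else 0L
    sph_body[i] <- 5L + b            # right foot (5) or toes (6)
    sph_body[i + 5] <- 9L + b        # left foot (9) or toes (10)
    sph_x[i] <- sph_x[i + 5] <- sph[[i]]$location[1]
    sph_y[i] <- sph_y[i + 5] <- sph[[i]]$location[2]
    sph_r[i] <- sph_r[i + 5] <- sph[[i]]$radius
  }

  cal <- model$calibration_pose
  qcal <- c(0, 0, 0, cal$hip, cal$knee, cal$ankle, cal$toe,
            cal$hip, cal$knee, cal$ankle, cal$toe)

  pv <- model$passive
  jd <- pv$joint_damping
  jdamp <- c(0, 0, 0, jd$hip, jd$knee, jd$ankle, jd$toe,
             jd$hip, jd$knee, jd$ankle, jd$toe)
  jstiff <- numeric(11)
  jstiff[c(7, 11)] <- pv$toe_stiffness

  mus <- model$muscles
  scale <- c(rep(1 - model$weakness[["right"]], 12),
             rep(1 - model$weakness[["left"]], 12))
  fmax <- rep(vapply(mus, `[[`, numeric(1), "f_iso_max"), 2) * scale
  arms <- matrix(0, 24, 11)
  for (i in seq_len(12)) {
    ma <- mus[[i]]$moment_arms
    for (j in names(ma)) {
      arms[i, .joint_cols$right[[j]]] <- ma[[j]]
      arms[i + 12, .joint_cols$left[[j]]] <- ma[[j]]
    }
  }
  rep2 <- function(field) rep(vapply(mus, `[[`, numeric(1), field), 2)
  list(parent = parent, jtype = jtype,
       axis_x = axis_x, axis_y = axis_y, axis_sign = axis_sign,
       anc_x = vapply(anchors, `[`, numeric(1), 1),
       anc_y = vapply(anchors, `[`, numeric(1), 2),
       mass = vapply(bodies, `[[`, numeric(1), "m"),
       com_x = vapply(bodies, function(b) b$com[1], numeric(1)),
       com_y = vapply(bodies, function(b) b$com[2], numeric(1)),
       izz = vapply(bodies, `[[`, numeric(1), "I"),
       gravity = model$gravity,
       sph_body = sph_body, sph_x = sph_x, sph_y = sph_y, sph_r = sph_r,
       stiffness = model$contact$stiffness,
       dissipation = model$contact$dissipation,
       friction = model$contact$friction,
       velocity_smoothing = model$contact$velocity_smoothing,
       depth_smoothing = model$contact$depth_smoothing,
       heel_r = 0L, heel_l = 5L,
       fmax = fmax,
       lopt = rep2("optimal_fiber_length"),
       lts = rep2("tendon_slack_length"),
       alpha0 = rep2("pennation_at_optimal"),
       vmax = rep2("max_contraction_velocity"),
       tau_a = rep2("activation_tau"),
       tau_d = rep2("deactivation_tau"),
       damping = rep2("fiber_damping"),
       ftfrac = rep2("fast_twitch_fraction"),
       mmass = rep2("muscle_mass"),
       arms = arms,
       jdamp = jdamp, jstiff = jstiff, qcal = qcal)
}

# external pointer to the compiled model, built lazily and cached
model_ptr <- function(model) {
  stopifnot(inherits(model, "gait_model"))
  p <- model$cache$ptr
  if (is.null(p) || !xptr_alive(p, function(pp) .model_body_mass_cpp(pp))) {
    p <- .model_build_cpp(model_flat(model))
    assign("ptr", p, envir = model$cache)
  }
  p
}

# external pointers do not survive serialization; probe and rebuild lazily
xptr_alive <- function(p, probe) {
  !isTRUE(tryCatch({ probe(p); FALSE }, error = function(e) TRUE))
}

muscle_names2 <- function(model) {
  c(paste0(names(model$muscles), "_r"), paste0(names(model$muscles), "_l"))
}
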