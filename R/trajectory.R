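# State/control layout shared with the compiled core:
#   X (70 x n): rows 1:11 q, 12:22 u, 23:46 a, 47:70 normalized tendon force
#   C (48 x n): rows 1:24 e, 25:48 d(tendon force)/dt
.NX <- 70L
.NU <- 48L

#' Construct a gait trajectory
#'
#' A trajectory holds the discretized states and controls of one stride on an
#' evenly spaced time grid: generalized coordinates `q` and velocities `u`
#' (11 each), muscle activations `a` and normalized tendon forces `ft`
#' (24 each), and the controls: excitations `e` and tendon-force derivatives
#' `dft`.
#'
#' @param tf final time (stride time), s.
#' @param q,u 11 x n matrices of coordinates and velocities.
#' @param a,ft 24 x n matrices of activations and normalized tendon forces.
#' @param e,dft 24 x n matrices of excitations and tendon-force derivatives.
#' @return an object of class `gait_trajectory`.
#' @export
gait_trajectory <- function(tf, q, u, a, ft, e, dft) {
  n <- ncol(q)
  stopifnot(nrow(q) == 11L, all(dim(u) == dim(q)),
            nrow(a) == 24L, ncol(a) == n, all(dim(ft) == dim(a)),
            all(dim(e) == dim(a)), all(dim(dft) == dim(a)),
            tf > 0)
  structure(list(n = n, tf = tf, times = seq(0, tf, length.out = n),
                 X = rbind(q, u, a, ft), C = rbind(e, dft)),
            class = "gait_trajectory")
}

traj_from_XC <- function(X, C, tf) {
  n <- ncol(X)
  structure(list(n = n, tf = tf, times = seq(0, tf, length.out = n),
                 X = X, C = C), class = "gait_trajectory")
}

#' Trajectory component accessors
#'
#' @param traj a `gait_trajectory`.
#' @return the requested component as a matrix (channels x nodes).
#' @export
traj_q <- function(traj) traj$X[1:11, , drop = FALSE]
#' @rdname traj_q
#' @export
traj_u <- function(traj) traj$X[12:22, , drop = FALSE]
#' @rdname traj_q
#' @export
traj_a <- function(traj) traj$X[23:46, , drop = FALSE]
#' @rdname traj_q
#' @export
traj_ft <- function(traj) traj$X[47:70, , drop = FALSE]
#' @rdname traj_q
#' @export
traj_e <- function(traj) traj$C[1:24, , drop = FALSE]
#' @rdname traj_q
#' @export
traj_dft <- function(traj) traj$C[25:48, , drop = FALSE]

#' @method print gait_trajectory
#' @export
print.gait_trajectory <- function(x, ...) {
  cat(sprintf("gait trajectory: %d nodes over %.3f s (%.1f ms spacing)\n",
              x$n, x$tf, 1000 * x$tf / (x$n - 1)))
  invisible(x)
}

#' Net forward pelvis displacement of a trajectory
#'
#' @param traj a `gait_trajectory` (at least two nodes).
#' @return displacement in metres: final minus initial forward pelvis position.
#' @export
pelvis_displacement <- function(traj) {
  stopifnot(inherits(traj, "gait_trajectory"), traj$n >= 2L)
  unname(traj$X[1, traj$n] - traj$X[1, 1])
}

#' Resample a trajectory to a new grid
#'
#' Periodic-phase cubic-spline interpolation of every state and control
#' channel; used to move solutions between grid resolutions and to build warm
#' starts.
#'
#' @param traj a `gait_trajectory`.
#' @param n_nodes new node count.
#' @param tf optional new final time (defaults to the trajectory's own).
#' @return a `gait_trajectory` on the new grid.
#' @export
resample_trajectory <- function(traj, n_nodes, tf = traj$tf) {
  ph_old <- seq(0, 1, length.out = traj$n)
  ph_new <- seq(0, 1, length.out = n_nodes)
  interp <- function(M) {
    t(apply(M, 1, function(y) spline(ph_old, y, xout = ph_new, method = "fmm")$y))
  }
  # pelvis forward travel is linear-plus-periodic: interpolate the deviation
  X <- traj$X
  v_slope <- (X[1, traj$n] - X[1, 1]) / traj$tf
  dev <- X[1, ] - v_slope * traj$times
  Xn <- interp(X)
  Xn[1, ] <- spline(ph_old, dev, xout = ph_new)$y + v_slope * tf * ph_new
  Cn <- interp(traj$C)
  traj_from_XC(Xn, Cn, tf)
}

# scaled decision vector <-> trajectory
traj_scales <- function() {
  # sd: characteristic rates per state channel, used to scale defect rows
  # (coordinate rates ~ speeds; joint accelerations grow distally, the toe
  # most of all because its segment is light and sits on stiff contact)
  sd_u <- c(10, 10, 20, 100, 200, 500, 2000, 100, 200, 500, 2000)
  list(sx = c(rep(1, 11), rep(5, 11), rep(1, 24), rep(1, 24)),
       su = c(rep(1, 24), rep(50, 24)),
       sd = c(rep(1, 11), sd_u, rep(10, 24), rep(20, 24)),
       stf = 1)
}

pack_z <- function(traj, scales = traj_scales()) {
  c(as.vector(traj$X / scales$sx), as.vector(traj$C / scales$su),
    traj$tf / scales$stf)
}

unpack_z <- function(z, n, scales = traj_scales()) {
  nx <- .NX * n
  X <- matrix(z[1:nx], .NX, n) * scales$sx
  C <- matrix(z[(nx + 1):(nx + .NU * n)], .NU, n) * scales$su
  traj_from_XC(X, C, z[length(z)] * scales$stf)
}

#' Export a trajectory as columnar text
#'
#' Writes time plus one named column per state/control channel,
#' tab-separated, with the final time recoverable from the time column.
#'
#' @param traj a `gait_trajectory`.
#' @param file output path.
#' @param model optional `gait_model` used for channel names.
#' @export
write_trajectory <- function(traj, file, model = NULL) {
  mn <- if (is.null(model)) sprintf("m%02d", 1:24) else muscle_names2(model)
  df <- data.frame(time = traj$times,
                   t(traj$X), t(traj$C), check.names = FALSE)
  names(df) <- c("time",
                 paste0("q.", coordinate_names), paste0("u.", coordinate_names),
                 paste0("a.", mn), paste0("ft.", mn),
                 paste0("e.", mn), paste0("dft.", mn))
  write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Import a trajectory written by [write_trajectory()]
#'
#' @param file path to a columnar trajectory file.
#' @return a `gait_trajectory`.
#' @export
read_trajectory <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  tm <- df[["time"]]
  M <- t(as.matrix(df[, -1, drop = FALSE]))
  traj_from_XC(M[1:.NX, , drop = FALSE],
               M[(.NX + 1):(.NX + .NU), , drop = FALSE],
               tf = tm[length(tm)])
}
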