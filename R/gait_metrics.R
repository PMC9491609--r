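#' Detect foot-strike events from vertical GRF traces
#'
#' A foot strike is the instant the vertical ground reaction force first
#' exceeds the threshold (default 20 N), located by linear interpolation
#' between the bracketing nodes; the periodic wrap from the last interval to
#' the first is included. Typically one strike per foot per stride is
#' expected; zero or multiple strikes flag the gait as atypical (a warning in
#' the result, not an error).
#'
#' @param grf 4 x n matrix (`fx_r, fy_r, fx_l, fy_l`) on the solution grid,
#'   or a list with per-foot vertical traces `fy_r`, `fy_l`.
#' @param times node times (length n); the last node wraps to the first.
#' @param config list with `vertical_force_threshold` (N), default 20.
#' @return list with strike times per foot (`right`, `left`), and
#'   `atypical` flags.
#' @export
detect_foot_strikes <- function(grf, times,
                                config = list(vertical_force_threshold = 20)) {
  thr <- config$vertical_force_threshold
  stopifnot(thr > 0)
  if (is.list(grf) && !is.matrix(grf)) {
    fy <- rbind(grf$fy_r, grf$fy_l)
  } else fy <- grf[c(2, 4), , drop = FALSE]
  n <- length(times)
  tf <- times[n]
  crossings <- function(y) {
    # periodic: drop duplicate last node, scan wrap interval too
    yv <- y[-n]
    tv <- times[-n]
    m <- length(yv)
    out <- numeric(0)
    for (k in seq_len(m)) {
      k2 <- if (k == m) 1L else k + 1L
      y1 <- yv[k]; y2 <- yv[k2]
      if (y1 <= thr && y2 > thr) {
        t1 <- tv[k]
        dt <- if (k == m) tf - tv[m] else tv[k + 1] - tv[k]
        out <- c(out, t1 + dt * (thr - y1) / (y2 - y1))
      }
    }
    out %% tf
  }
  right <- crossings(fy[1, ])
  left <- crossings(fy[2, ])
  list(right = right, left = left,
       atypical = c(right = length(right) != 1L, left = length(left) != 1L))
}

#' Spatiotemporal step metrics of a solved stride
#'
#' Step lengths are the fore-aft distance between the heel contact-sphere
#' centres at the instant of the respective foot strike (leading minus
#' trailing heel); the non-paretic (right) step time runs from paretic (left)
#' foot strike to non-paretic foot strike and the paretic step time from
#' non-paretic strike to paretic strike. Asymmetry indices follow [sla()] and
#' [sta()].
#'
#' @param traj a `gait_trajectory`.
#' @param model a `gait_model` (for heel kinematics and GRFs); alternatively
#'   supply precomputed `heel_x` and `grf` tracks.
#' @param events optional precomputed [detect_foot_strikes()] result.
#' @param heel_x optional 2 x n matrix of heel fore-aft positions
#'   (right, left).
#' @param grf optional 4 x n GRF matrix.
#' @param config foot-strike settings (see [detect_foot_strikes()]).
#' @return an object of class `gait_metrics`.
#' @export
step_metrics <- function(traj, model = NULL, events = NULL, heel_x = NULL,
                         grf = NULL,
                         config = list(vertical_force_threshold = 20)) {
  n <- traj$n; tf <- traj$tf
  if (is.null(heel_x) || is.null(grf)) {
    stopifnot(!is.null(model))
    ct <- .traj_contact_cpp(model_ptr(model), traj$X)
    if (is.null(heel_x)) heel_x <- ct$heel_x
    if (is.null(grf)) grf <- ct$grf
  }
  if (is.null(events)) events <- detect_foot_strikes(grf, traj$times, config)
  if (length(events$right) < 1L) stop("no foot strike detected for the right (non-paretic) foot")
  if (length(events$left) < 1L) stop("no foot strike detected for the left (paretic) foot")
  t_np <- events$right[1]
  t_p <- events$left[1]
  stride <- traj$X[1, n] - traj$X[1, 1]
  # heel positions advance by one stride per cycle: periodic interpolation of
  # the deviation from uniform travel
  heel_at <- function(row, t_) {
    dev <- heel_x[row, ] - stride * traj$times / tf
    devf <- stats::approx(traj$times, dev, xout = t_ %% tf)$y
    devf + stride * (t_ %% tf) / tf
  }
  sl_np <- heel_at(1, t_np) - heel_at(2, t_np)
  sl_p <- heel_at(2, t_p) - heel_at(1, t_p)
  # paretic strike leads or follows within the cycle; wrap durations
  st_p <- (t_p - t_np) %% tf     # non-paretic strike -> paretic strike
  st_np <- (t_np - t_p) %% tf    # paretic strike -> non-paretic strike
  structure(list(sl_np = sl_np, sl_p = sl_p, st_np = st_np, st_p = st_p,
                 sla = sla(sl_np, sl_p), sta = sta(st_np, st_p),
                 stride_time = tf, stride_length = stride,
                 mean_speed = stride / tf,
                 atypical = events$atypical, events = events),
            class = "gait_metrics")
}

#' @method print gait_metrics
#' @export
print.gait_metrics <- function(x, ...) {
  cat(sprintf("stride %.3f m in %.3f s (%.2f m/s)\n",
              x$stride_length, x$stride_time, x$mean_speed))
  cat(sprintf("  step length NP %.3f m, P %.3f m  (SLA %+.1f%%)\n",
              x$sl_np, x$sl_p, x$sla))
  cat(sprintf("  step time   NP %.3f s, P %.3f s  (STA %+.1f%%)\n",
              x$st_np, x$st_p, x$sta))
  if (any(x$atypical)) cat("  warning: atypical contact pattern\n")
  invisible(x)
}

#' @method as.data.frame gait_metrics
#' @export
as.data.frame.gait_metrics <- function(x, ...) {
  data.frame(sl_np = x$sl_np, sl_p = x$sl_p, st_np = x$st_np, st_p = x$st_p,
             sla = x$sla, sta = x$sta, stride_time = x$stride_time,
             stride_length = x$stride_length, mean_speed = x$mean_speed)
}

#' Summarize solved conditions and locate the optimal speed
#'
#' Collects per-condition step metrics and energetics into a tidy table and
#' reports, per model (weakness level), the speed minimizing metabolic cost
#' of transport. Ties within 1e-9 go to the slower speed; a model solved at a
#' single speed is flagged as an insufficient sweep.
#'
#' @param results data frame with at least `weakness`, `speed`, and `cot`
#'   columns (one row per solved condition), e.g. built from
#'   [summary.gait_solution()] outputs.
#' @return list with the input `table` and `optimal_speed` per weakness level.
#' @export
condition_summary <- function(results) {
  stopifnot(all(c("weakness", "speed", "cot") %in% names(results)))
  opt <- do.call(rbind, lapply(split(results, results$weakness), function(df) {
    df <- df[order(df$speed), ]
    best <- which(df$cot <= min(df$cot) + 1e-9)[1]  # tie -> slower speed
    data.frame(weakness = df$weakness[1], optimal_speed = df$speed[best],
               min_cot = df$cot[best], n_speeds = nrow(df),
               insufficient_sweep = nrow(df) < 2L)
  }))
  rownames(opt) <- NULL
  list(table = results[order(results$weakness, results$speed), ],
       optimal_speed = opt)
}
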