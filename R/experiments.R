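# Orchestration of the condition matrix: tracking solves seed nominal solves
# (per speed), nominal solutions seed their neighbours (guess ladder), and
# symmetry conditions reuse the nominal stride lengths as targets.

#' Build the experiment condition matrix
#'
#' The nominal matrix crosses the four weakness levels (0, 20, 40, 60%) with
#' five speeds (0.25 to 1.25 m/s); the symmetry conditions add the
#' step-length and step-length-plus-step-time variants at 0.75 m/s for the
#' three weakened models. An optional extra cell runs the symmetric model at
#' 1.50 m/s (to trace the U-shaped cost-speed curve).
#'
#' @param weakness weakness fractions; `speeds` target speeds (m/s).
#' @param symmetry include the six symmetry-goal conditions.
#' @param fast_symmetric include the symmetric-model 1.50 m/s cell.
#' @return data frame of conditions.
#' @export
condition_matrix <- function(weakness = c(0, 0.2, 0.4, 0.6),
                             speeds = c(0.25, 0.5, 0.75, 1.0, 1.25),
                             symmetry = TRUE, fast_symmetric = FALSE) {
  nominal <- expand.grid(weakness = weakness, speed = speeds,
                         objective = "nominal", stringsAsFactors = FALSE)
  out <- nominal
  if (fast_symmetric)
    out <- rbind(out, data.frame(weakness = 0, speed = 1.5, objective = "nominal"))
  if (symmetry) {
    wk <- setdiff(weakness, 0)
    out <- rbind(out,
                 expand.grid(weakness = wk, speed = 0.75, objective = "sl_sym",
                             stringsAsFactors = FALSE),
                 expand.grid(weakness = wk, speed = 0.75, objective = "sl_st_sym",
                             stringsAsFactors = FALSE))
  }
  out
}

#' Initial-guess ladder for one nominal condition
#'
#' Three guesses per condition: the tracking solution at the same speed, the
#' solution of the adjacent-faster-speed cell of the same model, and the
#' solution of the adjacent-greater-weakness cell at the same speed.
#'
#' @param weakness,speed the condition.
#' @param speeds,weaknesses the full sweep grids.
#' @return data frame of guess sources in priority order.
#' @export
guess_ladder <- function(weakness, speed,
                         speeds = c(0.25, 0.5, 0.75, 1.0, 1.25),
                         weaknesses = c(0, 0.2, 0.4, 0.6)) {
  lad <- data.frame(source = "tracking", weakness = weakness, speed = speed)
  sp <- sort(speeds)
  isp <- match(speed, sp)
  if (!is.na(isp) && isp < length(sp))
    lad <- rbind(lad, data.frame(source = "neighbor_speed", weakness = weakness,
                                 speed = sp[isp + 1]))
  wk <- sort(weaknesses)
  iwk <- match(weakness, wk)
  if (!is.na(iwk) && iwk < length(wk))
    lad <- rbind(lad, data.frame(source = "neighbor_weakness",
                                 weakness = wk[iwk + 1], speed = speed))
  lad
}

#' Run one experiment condition
#'
#' Solves a condition from every available guess in its ladder, keeps the
#' converged solution with the least objective ([select_best()]), and
#' computes its step metrics and energetic report. Solutions of previously
#' run conditions are pulled from (and added to) `store`, an environment
#' keyed by condition labels.
#'
#' @param model base (symmetric) `gait_model`.
#' @param weakness,speed,objective the condition cell.
#' @param store environment caching solutions across calls.
#' @param n_nodes,control solver settings.
#' @param reference optional `reference_gait` for the tracking stage.
#' @return a `gait_solution` (with `$energy` attached), or `NULL` with a
#'   warning when every guess fails.
#' @export
run_condition <- function(model, weakness, speed, objective = "nominal",
                          store = new.env(), n_nodes = 51L,
                          control = solver_control(), reference = NULL) {
  key <- function(w, s, o) sprintf("%s_w%02.0f_v%.2f", o, 100 * w, s)
  wmodel <- if (weakness > 0) apply_weakness(model, weakness) else model
  get_tracking <- function(s) {
    k <- key(0, s, "tracking")
    if (!is.null(store[[k]])) return(store[[k]])
    ref <- if (!is.null(reference)) reference else
      generate_reference(s, model = model)
    sol <- fit_gait(model, s, "tracking", n_nodes = n_nodes, reference = ref,
                    control = control, guess_label = "reference")
    store[[k]] <- sol
    sol
  }
  if (objective == "tracking") return(get_tracking(speed))
  if (objective %in% c("sl_sym", "sl_st_sym")) {
    nom <- store[[key(weakness, speed, "nominal")]]
    if (is.null(nom))
      nom <- run_condition(model, weakness, speed, "nominal", store,
                           n_nodes, control, reference)
    if (is.null(nom)) return(NULL)
    sol <- fit_gait(wmodel, speed, objective, n_nodes = n_nodes,
                    guess = nom$trajectory,
                    target_stride_length = nom$metrics$stride_length,
                    control = control, guess_label = "nominal warm start")
    if (!sol$converged) {
      warning("symmetry condition failed to converge: ",
              key(weakness, speed, objective))
    }
    sol$energy <- energy_report(sol$trajectory, wmodel)
    store[[key(weakness, speed, objective)]] <- sol
    return(sol)
  }
  # nominal: ladder of guesses
  lad <- guess_ladder(weakness, speed)
  sols <- list()
  for (i in seq_len(nrow(lad))) {
    g <- lad[i, ]
    guess <- if (g$source == "tracking") {
      tr <- tryCatch(get_tracking(g$speed), error = function(e) NULL)
      if (!is.null(tr)) tr$trajectory
    } else {
      prev <- store[[key(g$weakness, g$speed, "nominal")]]
      if (!is.null(prev)) prev$trajectory
    }
    if (is.null(guess)) next
    sol <- fit_gait(wmodel, speed, "nominal", n_nodes = n_nodes, guess = guess,
                    control = control, guess_label = g$source)
    sols <- c(sols, list(sol))
  }
  best <- tryCatch(select_best(sols), error = function(e) NULL)
  if (is.null(best)) {
    warning("all guesses failed for condition ", key(weakness, speed, "nominal"))
    return(NULL)
  }
  best$energy <- energy_report(best$trajectory, wmodel)
  store[[key(weakness, speed, "nominal")]] <- best
  best
}

#' Run a matrix of conditions
#'
#' Executes the requested cells in dependency order (tracking, nominal by
#' increasing weakness and decreasing speed, then symmetry conditions) and
#' collects tidy metric/energetic tables. Partial failures are reported in
#' the manifest and the run continues.
#'
#' @param model base `gait_model`.
#' @param conditions data frame from [condition_matrix()].
#' @param n_nodes,control solver settings.
#' @param out_dir optional directory for CSV outputs.
#' @return list with `manifest`, `metrics` table, `solutions` (environment).
#' @export
run_matrix <- function(model, conditions = condition_matrix(),
                       n_nodes = 51L, control = solver_control(),
                       out_dir = NULL) {
  store <- new.env()
  if (nrow(conditions) == 0L)
    return(list(manifest = data.frame(), metrics = data.frame(),
                solutions = store))
  ord <- order(match(conditions$objective, c("nominal", "sl_sym", "sl_st_sym")),
               conditions$weakness, -conditions$speed)
  conditions <- conditions[ord, , drop = FALSE]
  rows <- list(); manifest <- list()
  for (i in seq_len(nrow(conditions))) {
    cc <- conditions[i, ]
    sol <- tryCatch(
      run_condition(model, cc$weakness, cc$speed, cc$objective, store,
                    n_nodes, control),
      error = function(e) { warning(conditionMessage(e)); NULL })
    ok <- !is.null(sol) && isTRUE(sol$converged)
    manifest[[i]] <- data.frame(cc, converged = ok,
                                objective_value = if (ok) sol$objective_value else NA,
                                guess = if (!is.null(sol)) sol$guess_label else NA)
    if (!is.null(sol) && !is.null(sol$metrics)) {
      rows[[i]] <- data.frame(cc, as.data.frame(sol$metrics),
                              cot = sol$energy$cot[["total"]],
                              mech_cot_pos = sol$energy$mech_cot_pos[["total"]],
                              integrated_activation =
                                sol$energy$integrated_activation[["total"]])
    }
  }
  metrics <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  manifest <- do.call(rbind, manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(manifest = manifest, metrics = metrics, solutions = store)
}
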