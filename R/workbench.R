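#' Verify the behavioral calibration of a parameter set
#'
#' Runs the battery of behavioral checks that the packaged default
#' parameterization is required to pass:
#' \itemize{
#'   \item severe stress (`C_En = C_Nu = 0.1`), drug free: stationary with
#'     representative AV count in `[35, 39]`;
#'   \item moderate stress (0.6), drug free: oscillatory with envelope within
#'     `band_slack` of `[20, 27]`;
#'   \item replete (1.0), drug free: stationary with AV count below 5;
#'   \item dose directions at 0.6: constant doses of drugs 1 and 5 raise,
#'     and of drugs 2, 3, 4 and 6 lower, the representative AV count.
#' }
#'
#' @param params An [av_parameters()] object.
#' @param band_slack Allowed deviation of the oscillation envelope bounds
#'   from `[20, 27]` (AV units).
#' @param probe_dose Constant concentration (in units of each drug's
#'   `theta`) used for the direction checks.
#' @param ... Passed to [classify_long_time()].
#' @return A `calibration_report`: data frame of checks (name, measured
#'   value, target band, pass) with attribute `pass` (overall).
#' @export
verify_calibration <- function(params, band_slack = 1.5, probe_dose = 10,
                               ...) {
  validate_parameters(params)
  checks <- list()
  add <- function(name, value, lo, hi, pass = value >= lo & value <= hi)
    checks[[length(checks) + 1]] <<- data.frame(
      check = name, value = value, lo = lo, hi = hi, pass = pass)

  p <- params; p$C_En <- p$C_Nu <- 0.1
  s1 <- classify_long_time(p, ...)
  add("severe_stationary", as.numeric(s1$regime == "stationary"), 1, 1)
  add("severe_x5", s1$representative_x5, 35, 39)

  p$C_En <- p$C_Nu <- 0.6
  s6 <- classify_long_time(p, ...)
  add("moderate_oscillatory", as.numeric(s6$regime == "oscillatory"), 1, 1)
  add("moderate_env_min", s6$envelope[1], 20 - band_slack, 20 + band_slack)
  add("moderate_env_max", s6$envelope[2], 27 - band_slack, 27 + band_slack)

  p$C_En <- p$C_Nu <- 1
  s0 <- classify_long_time(p, ...)
  add("replete_stationary", as.numeric(s0$regime == "stationary"), 1, 1)
  add("replete_x5", s0$representative_x5, 0, 5)

  p$C_En <- p$C_Nu <- 0.6
  base <- s6$representative_x5
  for (drug in 1:6) {
    w <- rep(0, 6); w[drug] <- probe_dose * params$drugs[[drug]]$theta
    sd <- classify_long_time(p, doses = w, ...)
    delta <- sd$representative_x5 - base
    if (drug %in% c(1, 5)) {
      add(paste0("drug", drug, "_raises"), delta, 0.5, Inf)
    } else {
      add(paste0("drug", drug, "_lowers"), delta, -Inf, -0.5)
    }
  }
  out <- do.call(rbind, checks)
  structure(out, pass = all(out$pass),
            class = c("calibration_report", "data.frame"))
}

#' @export
print.calibration_report <- function(x, ...) {
  cat(sprintf("<calibration_report overall %s>\n",
              if (attr(x, "pass")) "PASS" else "FAIL"))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Packaged therapy-design scenario presets
#'
#' Named scenario presets reproducing the packaged therapy-design numerical
#' experiments: three monotherapies (drug 4 under severe stress, drugs 2 and
#' 5 under moderate stress) and four dual therapies built around drug 6. Caps
#' are either the absolute preset (`w_max = 2`) or `4 x EC50` at the
#' scenario's condition; both conventions appear in the reference analyses,
#' and the absolute preset is the default wherever both are plausible.
#'
#' @return Named list of preset definitions (condition, therapy, target,
#'   caps preset, horizon).
#' @export
scenario_presets <- function() {
  preset <- function(C, therapy, target, caps = "absolute2",
                     t0 = 120, tf = 240, epsilon = 1)
    list(condition = C, therapy = therapy, target = target, caps = caps,
         t0 = t0, tf = tf, epsilon = epsilon)
  list(
    `mono-drug4-severe`   = preset(0.1, 4, 10),
    `mono-drug2-moderate` = preset(0.6, 2, 10, caps = "4xEC50"),
    `mono-drug5-up`       = preset(0.6, 5, 37, caps = "4xEC50"),
    `dual-2-6-severe`     = preset(0.1, c(2, 6), 10),
    `dual-2-6-moderate`   = preset(0.6, c(2, 6), 10),
    `dual-3-6-moderate`   = preset(0.6, c(3, 6), 10),
    `dual-1-6-moderate`   = preset(0.6, c(1, 6), 10)
  )
}

#' Resolve a preset to an OCP specification
#'
#' @param name Preset name (see [scenario_presets()]).
#' @param params Parameter set; defaults to the packaged defaults.
#' @param ... Overrides passed on to [ocp_spec()].
#' @return An [ocp_spec()].
#' @export
resolve_preset <- function(name, params = default_parameters(), ...) {
  presets <- scenario_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         toString(names(presets)))
  pr <- presets[[name]]
  params$C_En <- params$C_Nu <- pr$condition
  w_max <- if (identical(pr$caps, "absolute2")) 2 else {
    4 * vapply(pr$therapy, function(d) as.numeric(compute_ec50(params, d)),
               numeric(1))
  }
  if (length(w_max) > 1L) {
    w_full <- rep(Inf, 6); w_full[pr$therapy] <- w_max; w_max <- w_full
  }
  ocp_spec(params, pr$therapy, target = pr$target, epsilon = pr$epsilon,
           t0 = pr$t0, tf = pr$tf, w_max = w_max, ...)
}

#' Run a therapy-design scenario end to end
#'
#' Resolves a preset (or accepts a ready [ocp_spec()]), solves the
#' minimum-fuel problem, validates the solution by re-integration, computes
#' optimality diagnostics when solved, and writes a solution bundle to a run
#' directory: a JSON manifest (scenario, N, seed, status, J, violations,
#' solver statistics) plus CSV tables of node values, interpolated
#' trajectory, schedule and cumulative dosages.
#'
#' @param scenario A preset name or an [ocp_spec()].
#' @param out_dir Output directory (created if missing).
#' @param params Parameter set for preset resolution.
#' @param N,seed,... Passed to [solve_ocp()].
#' @return The `ocp_solution`, invisibly; side effect: files in `out_dir`.
#' @export
run_scenario <- function(scenario, out_dir, params = default_parameters(),
                         N = 80, seed = 1L, ...) {
  spec <- if (inherits(scenario, "ocp_spec")) scenario else
    resolve_preset(scenario, params)
  name <- if (is.character(scenario)) scenario else "custom"
  sol <- solve_ocp(spec, N = N, seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (identical(sol$status, "infeasible")) {
    jsonlite::write_json(list(scenario = name, status = sol$status,
                              reason = sol$reason),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    stop("scenario '", name, "' infeasible: ", sol$reason)
  }
  manifest <- list(
    scenario = name, status = sol$status, N = N, seed = seed,
    therapy = spec$therapy, target = spec$target, epsilon = spec$epsilon,
    t0 = spec$t0, tf = spec$tf,
    w_max = spec$w_max[spec$therapy], u_max = sol$u_max,
    C_En = spec$params$C_En, C_Nu = spec$params$C_Nu,
    initial_state = as.numeric(spec$initial),
    J = sol$J, defect_norm = sol$defect_norm,
    band_violation = sol$feasibility$band_violation,
    cap_violation = max(sol$feasibility$cap_violation),
    outer_iterations = sol$outer_iterations,
    inner_evals = sol$inner_evals)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  nodes <- data.frame(t = sol$grid$times, sol$X, sol$U)
  names(nodes) <- c("t", STATE_NAMES, paste0("u", 1:6))
  utils::write.csv(nodes, file.path(out_dir, "nodes.csv"),
                   row.names = FALSE)
  write_trajectory_csv(sol$trajectory,
                       file.path(out_dir, "trajectory.csv"))
  sched <- data.frame(t = sol$schedule$times, sol$schedule$values)
  names(sched) <- c("t", paste0("u", 1:6))
  utils::write.csv(sched, file.path(out_dir, "schedule.csv"),
                   row.names = FALSE)
  utils::write.csv(sol$dosage, file.path(out_dir, "dosage.csv"),
                   row.names = FALSE)
  if (identical(sol$status, "solved")) {
    diag <- check_necessary_conditions(sol)
    sw <- data.frame(t = sol$grid$times, diag$switching)
    names(sw) <- c("t", paste0("sigma", spec$therapy))
    utils::write.csv(sw, file.path(out_dir, "switching.csv"),
                     row.names = FALSE)
  }
  if (!sol$status %in% c("solved")) {
    warning("scenario '", name, "' did not fully solve: status ",
            sol$status)
  }
  invisible(sol)
}
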