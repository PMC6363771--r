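#' Enumerate all size-k therapies
#'
#' All subsets of size `k` of the six available drug types, in lexicographic
#' order. There are `choose(6, k)` of them: six monotherapies, fifteen dual
#' therapies, and so on.
#'
#' @param k Number of drugs combined, integer in 1..6.
#' @return List of integer vectors (each sorted increasing).
#' @export
enumerate_therapies <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > 6)
    stop("'k' must be an integer between 1 and 6")
  m <- utils::combn(6, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

check_therapy <- function(therapy) {
  therapy <- as.integer(therapy)
  if (length(therapy) < 1L || anyDuplicated(therapy) ||
      !all(therapy %in% 1:6))
    stop("a therapy is a nonempty duplicate-free subset of drugs 1..6")
  sort(therapy)
}

#' Minimum-fuel objective of a schedule
#'
#' The unweighted sum over the therapy's drugs of the time integral of the
#' injection rate over `[0, tf]` (trapezoidal rule on the schedule grid,
#' refined with the interpolation rule of the schedule).
#'
#' @param schedule A [control_schedule()].
#' @param therapy Integer vector of drug indices.
#' @param tf End of the dosing horizon in minutes.
#' @param n_quad Number of quadrature samples.
#' @return Total drug used, a nonnegative number.
#' @export
schedule_objective <- function(schedule, therapy, tf, n_quad = 2001) {
  therapy <- check_therapy(therapy)
  if (any(schedule$values < 0)) stop("schedule has negative injection rates")
  # integrate exactly on the union of the schedule's breakpoints and a
  # uniform grid: exact for both interpolation rules of control_schedule
  tq <- sort(unique(c(pmin(pmax(schedule$times, 0), tf),
                      seq(0, tf, length.out = n_quad))))
  u <- eval_schedule(schedule, tq)
  dt <- diff(tq)
  sum(vapply(therapy, function(i) {
    y <- u[, i]
    if (schedule$interpolation == "constant") {
      sum(y[-length(y)] * dt)
    } else {
      sum((y[-1] + y[-length(y)]) / 2 * dt)
    }
  }, numeric(1)))
}

#' Cumulative dosage record
#'
#' The running integral `r_i(t)` of each therapy drug's injection rate from 0
#' to `t`, sampled on an output grid. For an optimal minimum-fuel schedule
#' this is the staircase-shaped total dosage curve.
#'
#' @param schedule A [control_schedule()].
#' @param therapy Integer vector of drug indices.
#' @param times Output grid (starting at 0).
#' @return A data frame with column `t` and one column `r<i>` per therapy
#'   drug; each `r<i>` starts at 0 and is nondecreasing.
#' @export
cumulative_dosage <- function(schedule, therapy, times) {
  therapy <- check_therapy(therapy)
  if (any(schedule$values < 0)) stop("schedule has negative injection rates")
  if (times[1] != 0) times <- c(0, times)
  tf <- max(times)
  # exact accumulation on the union of breakpoints and requested times;
  # the cumulative dosage is then read off at the requested times
  tq <- sort(unique(c(pmin(pmax(schedule$times, 0), tf), times)))
  u <- eval_schedule(schedule, tq)
  dt <- diff(tq)
  out <- data.frame(t = times)
  for (i in therapy) {
    y <- u[, i]
    inc <- if (schedule$interpolation == "constant") {
      y[-length(y)] * dt
    } else {
      (y[-1] + y[-length(y)]) / 2 * dt
    }
    cum <- c(0, cumsum(inc))
    out[[paste0("r", i)]] <- stats::approx(tq, cum, xout = times,
                                           rule = 2)$y
  }
  out
}

#' Optimal-control problem specification
#'
#' Bundles a target-control problem: drive the AV count `x5` from a drug-free
#' baseline state into the band `x5f +/- epsilon` and hold it there over the
#' maintenance window `[t0, tf]`, using only the therapy's drugs, with per-drug
#' concentration caps and nonnegative injection rates, while minimizing the
#' total amount of drug injected over `[0, tf]`.
#'
#' The initial state must be drug free (`w(0) = 0`). If `initial` is omitted
#' it is computed as the state reached after `burn_in` minutes of drug-free
#' dynamics from mid-box (a stationary point, or a recorded point on the limit
#' cycle when the baseline is oscillatory).
#'
#' @param params An [av_parameters()] object (the condition `C_En`, `C_Nu` is
#'   taken from it; availability flags are derived from `therapy`).
#' @param therapy Integer vector of drug indices (1..6).
#' @param target Target AV count `x5f`, strictly inside `(0, k3/k4)`.
#' @param epsilon Half-width of the tolerance band (default 1 AV).
#' @param t0 Start of the maintenance window, minutes (default 120).
#' @param tf End of the horizon, minutes (default 240).
#' @param w_max Per-drug concentration caps: either a single number applied
#'   to every therapy drug or a length-6 vector.
#' @param initial Optional length-11 initial state with zero drug
#'   concentrations.
#' @param burn_in Burn-in used when computing the default initial state.
#' @param one_sided If `TRUE`, only the upper (for downregulation targets
#'   below the baseline) band bound is enforced, admitting oscillatory
#'   solutions; default keeps both bounds.
#' @return An object of class `ocp_spec`.
#' @export
ocp_spec <- function(params, therapy, target, epsilon = 1, t0 = 120,
                     tf = 240, w_max = 2, initial = NULL, burn_in = 2000,
                     one_sided = FALSE) {
  validate_parameters(params)
  therapy <- check_therapy(therapy)
  if (!(t0 > 0 && tf > t0)) stop("need 0 < t0 < tf")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  ceil <- av_ceiling(params)
  if (target <= 0 || target >= ceil)
    stop(sprintf("target must lie inside (0, %g)", ceil))
  if (!one_sided && (target - epsilon < 0 || target + epsilon > ceil))
    stop("target band must lie inside [0, k3/k4]")
  if (length(w_max) == 1L) {
    w_full <- rep(Inf, 6); w_full[therapy] <- w_max
  } else {
    stopifnot(length(w_max) == 6L)
    w_full <- w_max
  }
  if (any(w_full[therapy] <= 0)) stop("concentration caps must be positive")
  params$b <- as.numeric(1:6 %in% therapy)
  if (is.null(initial)) {
    tr <- simulate_model(params, av_state(c(0.5, 0.5, 0.5, 0.5, ceil / 2),
                                          params = params),
                         times = seq(0, burn_in, by = 1))
    initial <- as.numeric(tr[nrow(tr), -1])
  }
  initial <- as.numeric(initial)
  if (length(initial) != 11L) stop("initial state must have 11 components")
  if (any(abs(initial[6:11]) > 1e-9))
    stop("initial drug concentrations must all be zero")
  initial[6:11] <- 0
  names(initial) <- STATE_NAMES
  structure(list(params = params, therapy = therapy, target = target,
                 epsilon = epsilon, t0 = t0, tf = tf, w_max = w_full,
                 initial = initial, one_sided = one_sided),
            class = "ocp_spec")
}

#' @export
print.ocp_spec <- function(x, ...) {
  cat(sprintf(paste0("<ocp_spec therapy {%s} target %g +/- %g on ",
                     "[%g, %g] min, C_En=%g C_Nu=%g>\n"),
              toString(x$therapy), x$target, x$epsilon, x$t0, x$tf,
              x$params$C_En, x$params$C_Nu))
  invisible(x)
}

#' Validate a candidate schedule against an OCP specification
#'
#' Re-integrates the full model under the (interpolated) schedule with a
#' high-accuracy adaptive solver, independently of any collocation grid, and
#' reports the magnitudes of all constraint violations together with the
#' objective value.
#'
#' @param spec An [ocp_spec()].
#' @param schedule A [control_schedule()] defined on `[0, tf]`.
#' @param n_check Number of evaluation times used for the violation maxima.
#' @param rtol,atol Integration tolerances for the re-integration.
#' @return A `feasibility_report`: list with `band_violation` (max excess of
#'   `|x5 - target| - epsilon` over `[t0, tf]`), per-drug `cap_violation`,
#'   `negativity_violation`, objective `J`, and the re-integrated
#'   `trajectory`.
#' @export
validate_solution <- function(spec, schedule, n_check = 1201,
                              rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(spec, "ocp_spec"))
  times <- seq(0, spec$tf, length.out = n_check)
  tr <- simulate_model(spec$params, spec$initial, schedule, times,
                       rtol = rtol, atol = atol)
  x5 <- tr$x5
  in_window <- tr$t >= spec$t0 - 1e-9
  over <- x5 - (spec$target + spec$epsilon)
  under <- (spec$target - spec$epsilon) - x5
  if (spec$one_sided) {
    dev <- if (spec$target <= spec$initial[5]) over else under
  } else {
    dev <- pmax(over, under)
  }
  band_violation <- max(0, dev[in_window])
  W <- as.matrix(tr[paste0("w", 1:6)])
  cap_violation <- vapply(1:6, function(i)
    max(0, max(W[, i]) - spec$w_max[i]), numeric(1))
  negativity_violation <- max(0, -min(schedule$values))
  J <- schedule_objective(schedule, spec$therapy, spec$tf)
  structure(list(band_violation = band_violation,
                 cap_violation = cap_violation,
                 negativity_violation = negativity_violation,
                 J = J, trajectory = tr),
            class = "feasibility_report")
}

#' @export
print.feasibility_report <- function(x, ...) {
  cat(sprintf(paste0("<feasibility_report J=%.4f band=%.3g cap=%.3g ",
                     "neg=%.3g>\n"),
              x$J, x$band_violation, max(x$cap_violation),
              x$negativity_violation))
  invisible(x)
}

#' Embed a schedule into a larger therapy
#'
#' A feasible monotherapy schedule, extended with zero injection for the
#' extra drugs, remains feasible for any therapy set containing it; this
#' helper produces the extended schedule (the schedule matrix already carries
#' all six drugs, so embedding only relaxes which columns are considered
#' active).
#'
#' @param schedule A [control_schedule()].
#' @param spec An [ocp_spec()] whose therapy is a superset of the drugs
#'   actually dosed in `schedule`.
#' @return The schedule, unchanged but checked for consistency.
#' @export
embed_schedule <- function(schedule, spec) {
  active <- which(colSums(schedule$values) > 0)
  if (!all(active %in% spec$therapy))
    stop("schedule doses drugs outside the target therapy set")
  schedule
}
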