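#' Classify long-time behavior
#'
#' Integrates past a burn-in horizon and over an observation window, then
#' classifies the attractor of the AV count `x5`: `"oscillatory"` if the
#' peak-to-peak amplitude over the window exceeds `osc_threshold`, otherwise
#' `"stationary"`. Coexistence of attractors is probed with a fixed set of
#' initial conditions spanning the state box (plus the drug-free fixed
#' point); if the regime call differs across probes the summary regime is
#' `"coexistence"` and the fields describe the default-probe attractor.
#'
#' The representative value is the time average over an integer number of
#' detected periods when oscillatory (peak-to-peak timing), else the terminal
#' value. A still-drifting amplitude (difference between the first and second
#' half of the window beyond `drift_tol`) is flagged in `$settled`.
#'
#' @param params An [av_parameters()] object.
#' @param doses Length-6 vector of constant drug concentrations, held fixed
#'   (pharmacokinetics bypassed); default drug free.
#' @param burn_in,observe Burn-in and observation horizons, minutes.
#' @param osc_threshold Peak-to-peak `x5` amplitude separating stationary
#'   from oscillatory calls (AV units).
#' @param probe_coexistence If `TRUE` (default for drug-free calls via
#'   [phase_diagram()]), run the multi-start probe.
#' @param drift_tol Allowed drift of the envelope between window halves.
#' @param rtol,atol Integration tolerances.
#' @return A `behavior_summary`: list with `regime`, `representative_x5`,
#'   `envelope` (min, max), `amplitude`, `period` (NA if stationary),
#'   `transient_time`, `settled`, and the probe terminal state.
#' @export
classify_long_time <- function(params, doses = rep(0, 6), burn_in = 2000,
                               observe = 1000, osc_threshold = 0.5,
                               probe_coexistence = FALSE, drift_tol = 0.25,
                               rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  stopifnot(length(doses) == 6L, all(doses >= 0))
  base <- run_probe(params, doses, NULL, burn_in, observe, osc_threshold,
                    drift_tol, rtol, atol)
  regime <- base$regime
  if (probe_coexistence) {
    ceil <- av_ceiling(params)
    probes <- list(c(0, 0, 0, 0, 0), c(1, 1, 1, 1, ceil),
                   c(1, 0, 1, 0, ceil / 4), c(0, 1, 0, 1, 3 * ceil / 4),
                   find_fixed_point(params)[1:5])
    calls <- vapply(probes, function(y0) {
      run_probe(params, doses, y0, burn_in, observe, osc_threshold,
                drift_tol, rtol, atol)$regime
    }, character(1))
    if (length(unique(c(base$regime, calls))) > 1L) regime <- "coexistence"
  }
  structure(c(list(regime = regime), base[-1]), class = "behavior_summary")
}

run_probe <- function(params, doses, y0, burn_in, observe, osc_threshold,
                      drift_tol, rtol, atol) {
  if (is.null(y0)) y0 <- c(0.5, 0.5, 0.5, 0.5, av_ceiling(params) / 2)
  init <- av_state(y0, w = doses, params = params)
  step <- 0.5
  tr <- simulate_model(params, init, times = seq(0, burn_in + observe, by = step),
                       fixed_w = doses, rtol = rtol, atol = atol)
  obs <- tr[tr$t >= burn_in, ]
  x5 <- obs$x5
  env <- range(x5)
  amp <- diff(env)
  oscillatory <- amp > osc_threshold
  # drift check: envelope of the two window halves should agree
  half <- x5[seq_len(floor(length(x5) / 2))]
  rest <- x5[-seq_len(floor(length(x5) / 2))]
  settled <- max(abs(range(half) - range(rest))) <= drift_tol + osc_threshold *
    (!oscillatory)
  period <- NA_real_
  if (oscillatory) {
    pk <- find_peaks(obs$t, x5)
    if (length(pk) >= 3) {
      period <- mean(diff(pk))
      # average over the integer number of periods between first/last peak
      keep <- obs$t >= pk[1] & obs$t <= pk[length(pk)]
      rep_x5 <- mean(x5[keep])
    } else rep_x5 <- mean(x5)
  } else rep_x5 <- x5[length(x5)]
  list(regime = if (oscillatory) "oscillatory" else "stationary",
       representative_x5 = rep_x5, envelope = env, amplitude = amp,
       period = period,
       transient_time = transient_time(tr, rep_x5, amp, osc_threshold),
       settled = settled,
       terminal_state = as.numeric(obs[nrow(obs), -1]))
}

# interior local maxima of a sampled signal
find_peaks <- function(t, y) {
  n <- length(y)
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1
  t[idx]
}

# first time after which x5 stays within the attractor band
transient_time <- function(tr, rep_x5, amp, osc_threshold) {
  band <- max(amp, osc_threshold) / 2 + 0.5
  inside <- abs(tr$x5 - rep_x5) <= band
  last_out <- max(c(0, tr$t[!inside]))
  min(last_out, max(tr$t))
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("<behavior_summary %s x5=%.2f envelope=[%.2f, %.2f]>\n",
              x$regime, x$representative_x5, x$envelope[1], x$envelope[2]))
  invisible(x)
}

#' Phase diagram over the energy/nutrient plane
#'
#' Runs [classify_long_time()] (drug free) on every cell of a grid of
#' energy/nutrient supplies and collects the summaries in tidy form.
#'
#' @param params An [av_parameters()] object (its own `C_En`, `C_Nu` are
#'   overridden cell by cell).
#' @param c_en_grid,c_nu_grid Increasing sequences in `[0, 1]`.
#' @param ... Passed to [classify_long_time()] (e.g. shorter horizons or
#'   looser tolerances for coarse scans).
#' @return A `phase_diagram`: data frame with one row per cell and columns
#'   `C_En`, `C_Nu`, `regime`, `representative_x5`, `env_min`, `env_max`,
#'   `amplitude`, `settled`.
#' @export
phase_diagram <- function(params, c_en_grid, c_nu_grid, ...) {
  stopifnot(all(c_en_grid >= 0 & c_en_grid <= 1),
            all(c_nu_grid >= 0 & c_nu_grid <= 1))
  cells <- expand.grid(C_En = c_en_grid, C_Nu = c_nu_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(j) {
    p <- params
    p$C_En <- cells$C_En[j]; p$C_Nu <- cells$C_Nu[j]
    s <- classify_long_time(p, ...)
    data.frame(C_En = p$C_En, C_Nu = p$C_Nu, regime = s$regime,
               representative_x5 = s$representative_x5,
               env_min = s$envelope[1], env_max = s$envelope[2],
               amplitude = s$amplitude, settled = s$settled)
  })
  structure(do.call(rbind, rows),
            class = c("phase_diagram", "data.frame"))
}

#' Step response to an energy/nutrient switch
#'
#' Equilibrates the drug-free system at one condition (burn-in), then follows
#' the trajectory after an instantaneous switch to a second condition.
#'
#' @param params An [av_parameters()] object.
#' @param before,after Length-2 vectors `(C_En, C_Nu)`.
#' @param horizon Post-switch horizon in minutes.
#' @param burn_in Pre-switch equilibration time.
#' @param dt Output sampling interval.
#' @return An `av_trajectory` starting at the switch (t = 0).
#' @export
step_response <- function(params, before, after, horizon = 500,
                          burn_in = 2000, dt = 0.5) {
  p0 <- params; p0$C_En <- before[1]; p0$C_Nu <- before[2]
  p1 <- params; p1$C_En <- after[1]; p1$C_Nu <- after[2]
  validate_parameters(p0); validate_parameters(p1)
  eq <- simulate_model(p0, av_state(c(0.5, 0.5, 0.5, 0.5,
                                      av_ceiling(p0) / 2), params = p0),
                       times = seq(0, burn_in, by = 1))
  y0 <- as.numeric(eq[nrow(eq), -1])
  simulate_model(p1, y0, times = seq(0, horizon, by = dt))
}

#' Dose-response curve for constant monotherapy
#'
#' Holds one drug's concentration fixed at each dose of a grid (bypassing
#' pharmacokinetics) and classifies the long-time behavior per dose.
#'
#' @param params An [av_parameters()] object (condition taken from it).
#' @param drug Drug index 1..6.
#' @param doses Increasing nonnegative dose grid; must start at 0 so the
#'   zero-dose entry reproduces the drug-free behavior.
#' @param ... Passed to [classify_long_time()].
#' @return A `dose_response` data frame with columns `dose`, `regime`,
#'   `representative_x5`, `env_min`, `env_max`, `amplitude`, `settled`.
#' @export
dose_response <- function(params, drug, doses, ...) {
  if (!(length(drug) == 1L && drug %in% 1:6)) stop("invalid drug index")
  if (doses[1] != 0) stop("dose grid must start at 0")
  if (any(diff(doses) <= 0) || any(doses < 0))
    stop("doses must be increasing and nonnegative")
  rows <- lapply(doses, function(d) {
    w <- rep(0, 6); w[drug] <- d
    s <- classify_long_time(params, doses = w, ...)
    data.frame(dose = d, regime = s$regime,
               representative_x5 = s$representative_x5,
               env_min = s$envelope[1], env_max = s$envelope[2],
               amplitude = s$amplitude, settled = s$settled)
  })
  out <- do.call(rbind, rows)
  attr(out, "drug") <- drug
  attr(out, "condition") <- c(C_En = params$C_En, C_Nu = params$C_Nu)
  structure(out, class = c("dose_response", "data.frame"))
}

#' EC50 of a drug's long-time effect on the AV count
#'
#' The constant concentration at which the drug's effect on the long-time
#' (representative) AV count, negative or positive, is half of its saturating
#' magnitude. A logarithmic dose scan spanning
#' `[scan_span[1], scan_span[2]] * theta` of the drug's Hill curve brackets
#' the half-maximal effect; bisection refines the crossing to relative width
#' `rel_tol`.
#'
#' @param params An [av_parameters()] object (condition taken from it).
#' @param drug Drug index 1..6.
#' @param n_scan Number of scan doses (logarithmically spaced).
#' @param scan_span Multiplicative span of the scan around `theta`.
#' @param rel_tol Relative width at which bisection stops.
#' @param min_effect Smallest saturating |effect| (AV units) considered
#'   measurable; a flatter response raises an error.
#' @param monotone_tol Tolerated non-monotonicity of the scanned effect, as
#'   a fraction of the saturating magnitude (biphasic responses below this
#'   fraction, e.g. the low-dose autophagy rise under a dual-specificity
#'   MTORC1/VPS34 inhibitor, are tolerated).
#' @param ... Passed to [classify_long_time()].
#' @return The EC50 concentration (positive number), with the scanned doses
#'   and effects attached as attributes.
#' @export
compute_ec50 <- function(params, drug, n_scan = 25,
                         scan_span = c(1e-3, 1e3), rel_tol = 1e-3,
                         min_effect = 1, monotone_tol = 0.25, ...) {
  if (!(length(drug) == 1L && drug %in% 1:6)) stop("invalid drug index")
  theta <- params$drugs[[drug]]$theta
  effect_at <- function(d) {
    w <- rep(0, 6); w[drug] <- d
    classify_long_time(params, doses = w, ...)$representative_x5
  }
  base <- effect_at(0)
  scan <- exp(seq(log(scan_span[1] * theta), log(scan_span[2] * theta),
                  length.out = n_scan))
  eff <- vapply(scan, effect_at, numeric(1)) - base
  sat <- eff[length(eff)]
  if (abs(sat) < min_effect)
    stop("no measurable effect: saturating magnitude ",
         sprintf("%.3g", abs(sat)), " below threshold")
  signed <- eff * sign(sat)
  viol <- which(diff(signed) < -monotone_tol * abs(sat))
  if (length(viol))
    stop("non-monotone dose response between doses ",
         toString(sprintf("%.3g", scan[c(viol[1], viol[1] + 1)])))
  half <- abs(sat) / 2
  above <- which(signed >= half)
  if (!length(above)) stop("half-maximal effect not bracketed by the scan")
  hi <- scan[above[1]]
  lo <- if (above[1] == 1) 0 else scan[above[1] - 1]
  while ((hi - lo) > rel_tol * hi) {
    mid <- if (lo == 0) hi / 2 else sqrt(lo * hi)
    if ((effect_at(mid) - base) * sign(sat) >= half) hi <- mid else lo <- mid
  }
  ec50 <- (lo + hi) / 2
  attr(ec50, "scan") <- data.frame(dose = scan, effect = eff)
  attr(ec50, "baseline_x5") <- base
  ec50
}

#' Export a phase diagram or dose-response table to CSV
#' @param x A `phase_diagram` or `dose_response` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_behavior_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
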