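STATE_NAMES <- c(paste0("x", 1:5), paste0("w", 1:6))

#' System state constructor
#'
#' Assembles and validates the 11-dimensional model state: active kinase
#' fractions `x1..x4` (MTORC1, ULK1, AMPK, VPS34) in `[0, 1]`, the AV count
#' `x5` in `[0, k3/k4]`, and six nonnegative dimensionless drug
#' concentrations `w1..w6`.
#'
#' @param x Numeric length-5 vector `x1..x5`.
#' @param w Numeric length-6 vector `w1..w6` (default: drug free).
#' @param params An [av_parameters()] object (used for the `x5` bound).
#' @param tol Tolerance: values within `tol` outside the box are clipped;
#'   larger violations raise an error.
#' @return A named numeric vector of length 11 with class `av_state`.
#' @export
av_state <- function(x, w = rep(0, 6), params, tol = 1e-6) {
  stopifnot(length(x) == 5L, length(w) == 6L)
  s <- c(x, w)
  names(s) <- STATE_NAMES
  clip_state(s, params, tol = tol)
}

# clip values within tol outside the state box; error on larger violations
clip_state <- function(s, params, tol = 1e-6) {
  lo <- state_lower(params)
  hi <- state_upper(params)
  if (any(s < lo - tol) || any(s > hi + tol)) {
    bad <- STATE_NAMES[s < lo - tol | s > hi + tol]
    stop("state outside admissible box beyond tolerance: ", toString(bad))
  }
  structure(pmin(pmax(s, lo), hi), names = STATE_NAMES, class = "av_state")
}

state_lower <- function(params) rep(0, 11)
state_upper <- function(params)
  c(rep(1, 4), av_ceiling(params), rep(Inf, 6))

# drug multipliers H_i(w_i) for a length-6 concentration vector
drug_multipliers <- function(w, params)
  vapply(1:6, function(i) hill_drug(w[i], params$drugs[[i]]), numeric(1))

#' Model vector field
#'
#' Right-hand side of the coupled kinase-network + pharmacokinetics ODE
#' system. Writing `h*` for the activating regulation curves and `H_i` for
#' the drug multipliers, the components are (each divided by the timescale T):
#' \preformatted{
#' T dx1/dt = (1 - x1) C_Nu H1(w1) H2(w2) - x1 h12(x2) h13(x3)
#' T dx2/dt = (1 - x2) h23(x3) H3(w3)     - x2 h21(x1)
#' T dx3/dt = (1 - x3) k1 H4(w4)          - C_En x2 x3 H5(w5)
#' T dx4/dt = (1 - x4) h42(x2) H2(w2) H6(w6) - k2 x4
#' T dx5/dt = k3 x4 - k4 x5
#' T dwi/dt = b_i u_i - delta_i w_i,  i = 1..6
#' }
#'
#' @param state Named numeric length-11 state (see [av_state()]).
#' @param controls Numeric length-6 vector of nonnegative injection rates.
#' @param params An [av_parameters()] object.
#' @return Named numeric length-11 derivative.
#' @export
av_vector_field <- function(state, controls = rep(0, 6), params) {
  stopifnot(length(state) == 11L, length(controls) == 6L)
  if (any(controls < 0)) stop("negative control input")
  x1 <- state[[1]]; x2 <- state[[2]]; x3 <- state[[3]]
  x4 <- state[[4]]; x5 <- state[[5]]
  w <- unname(state[6:11])
  H <- drug_multipliers(w, params)
  r <- params$regulation
  d <- c(
    (1 - x1) * params$C_Nu * H[1] * H[2] -
      x1 * hill_activating(x2, r$h12) * hill_activating(x3, r$h13),
    (1 - x2) * hill_activating(x3, r$h23) * H[3] -
      x2 * hill_activating(x1, r$h21),
    (1 - x3) * params$k1 * H[4] - params$C_En * x2 * x3 * H[5],
    (1 - x4) * hill_activating(x2, r$h42) * H[2] * H[6] - params$k2 * x4,
    params$k3 * x4 - params$k4 * x5,
    params$b * controls - params$delta * w)
  names(d) <- STATE_NAMES
  d / params$timescale
}

# Vectorized vector field over node columns.
# X: 11 x m matrix of states, U: 6 x m matrix of controls. Returns 11 x m.
vector_field_nodes <- function(X, U, params) {
  m <- ncol(X)
  r <- params$regulation
  H <- matrix(0, 6, m)
  for (i in 1:6) H[i, ] <- hill_drug(X[5 + i, ], params$drugs[[i]])
  out <- matrix(0, 11, m)
  out[1, ] <- (1 - X[1, ]) * params$C_Nu * H[1, ] * H[2, ] -
    X[1, ] * hill_activating(X[2, ], r$h12) * hill_activating(X[3, ], r$h13)
  out[2, ] <- (1 - X[2, ]) * hill_activating(X[3, ], r$h23) * H[3, ] -
    X[2, ] * hill_activating(X[1, ], r$h21)
  out[3, ] <- (1 - X[3, ]) * params$k1 * H[4, ] -
    params$C_En * X[2, ] * X[3, ] * H[5, ]
  out[4, ] <- (1 - X[4, ]) * hill_activating(X[2, ], r$h42) * H[2, ] * H[6, ] -
    params$k2 * X[4, ]
  out[5, ] <- params$k3 * X[4, ] - params$k4 * X[5, ]
  for (i in 1:6) out[5 + i, ] <- params$b[i] * U[i, ] - params$delta[i] *
    X[5 + i, ]
  out / params$timescale
}

# Jacobians of the vector field at every node.
# Returns list(Jx = array 11 x 11 x m, Ju = array 11 x 6 x m).
vector_field_jacobian_nodes <- function(X, U, params) {
  m <- ncol(X)
  r <- params$regulation
  H <- matrix(0, 6, m); dH <- matrix(0, 6, m)
  for (i in 1:6) {
    H[i, ] <- hill_drug(X[5 + i, ], params$drugs[[i]])
    dH[i, ] <- hill_drug_deriv(X[5 + i, ], params$drugs[[i]])
  }
  h12 <- hill_activating(X[2, ], r$h12); d12 <- hill_activating_deriv(X[2, ], r$h12)
  h13 <- hill_activating(X[3, ], r$h13); d13 <- hill_activating_deriv(X[3, ], r$h13)
  h23 <- hill_activating(X[3, ], r$h23); d23 <- hill_activating_deriv(X[3, ], r$h23)
  h21 <- hill_activating(X[1, ], r$h21); d21 <- hill_activating_deriv(X[1, ], r$h21)
  h42 <- hill_activating(X[2, ], r$h42); d42 <- hill_activating_deriv(X[2, ], r$h42)
  Jx <- array(0, c(11, 11, m)); Ju <- array(0, c(11, 6, m))
  Tinv <- 1 / params$timescale
  # row 1
  Jx[1, 1, ] <- (-params$C_Nu * H[1, ] * H[2, ] - h12 * h13) * Tinv
  Jx[1, 2, ] <- (-X[1, ] * d12 * h13) * Tinv
  Jx[1, 3, ] <- (-X[1, ] * h12 * d13) * Tinv
  Jx[1, 6, ] <- ((1 - X[1, ]) * params$C_Nu * dH[1, ] * H[2, ]) * Tinv
  Jx[1, 7, ] <- ((1 - X[1, ]) * params$C_Nu * H[1, ] * dH[2, ]) * Tinv
  # row 2
  Jx[2, 1, ] <- (-X[2, ] * d21) * Tinv
  Jx[2, 2, ] <- (-h23 * H[3, ] - h21) * Tinv
  Jx[2, 3, ] <- ((1 - X[2, ]) * d23 * H[3, ]) * Tinv
  Jx[2, 8, ] <- ((1 - X[2, ]) * h23 * dH[3, ]) * Tinv
  # row 3
  Jx[3, 2, ] <- (-params$C_En * X[3, ] * H[5, ]) * Tinv
  Jx[3, 3, ] <- (-params$k1 * H[4, ] - params$C_En * X[2, ] * H[5, ]) * Tinv
  Jx[3, 9, ] <- ((1 - X[3, ]) * params$k1 * dH[4, ]) * Tinv
  Jx[3, 10, ] <- (-params$C_En * X[2, ] * X[3, ] * dH[5, ]) * Tinv
  # row 4
  Jx[4, 2, ] <- ((1 - X[4, ]) * d42 * H[2, ] * H[6, ]) * Tinv
  Jx[4, 4, ] <- (-h42 * H[2, ] * H[6, ] - params$k2) * Tinv
  Jx[4, 7, ] <- ((1 - X[4, ]) * h42 * dH[2, ] * H[6, ]) * Tinv
  Jx[4, 11, ] <- ((1 - X[4, ]) * h42 * H[2, ] * dH[6, ]) * Tinv
  # row 5
  Jx[5, 4, ] <- params$k3 * Tinv
  Jx[5, 5, ] <- -params$k4 * Tinv
  # drug rows
  for (i in 1:6) {
    Jx[5 + i, 5 + i, ] <- -params$delta[i] * Tinv
    Ju[5 + i, i, ] <- params$b[i] * Tinv
  }
  list(Jx = Jx, Ju = Ju)
}

#' Drug injection schedule
#'
#' Represents the six per-drug injection-rate functions `u_i(t)` as samples on
#' a common time grid with a stated interpolation rule (piecewise linear by
#' default, or piecewise constant).
#'
#' @param times Strictly increasing time grid in minutes.
#' @param values Matrix with `length(times)` rows and 6 columns of
#'   nonnegative injection rates (a vector is accepted for a single column
#'   repeated; a matrix with fewer columns must be accompanied by `drugs`).
#' @param drugs Optional integer vector naming which drug each column of
#'   `values` controls; remaining drugs get zero schedules.
#' @param interpolation `"linear"` or `"constant"`.
#' @return An object of class `control_schedule`.
#' @export
control_schedule <- function(times, values, drugs = NULL,
                             interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  if (nrow(values) != length(times))
    stop("'values' must have one row per time sample")
  if (any(values < 0)) stop("injection rates must be nonnegative")
  full <- matrix(0, length(times), 6)
  if (is.null(drugs)) {
    if (ncol(values) != 6L)
      stop("supply a 6-column 'values' matrix or a 'drugs' index vector")
    full <- values
  } else {
    stopifnot(length(drugs) == ncol(values), all(drugs %in% 1:6))
    full[, drugs] <- values
  }
  structure(list(times = as.numeric(times), values = full,
                 interpolation = interpolation),
            class = "control_schedule")
}

#' The all-zero (drug-free) schedule
#' @param t_end End of the schedule domain in minutes.
#' @return A [control_schedule()] that is identically zero on `[0, t_end]`.
#' @export
zero_schedule <- function(t_end)
  control_schedule(c(0, t_end), matrix(0, 2, 6))

#' Evaluate a schedule
#' @param schedule A [control_schedule()].
#' @param t Numeric vector of times (clamped to the schedule domain).
#' @return Matrix `length(t)` x 6 of injection rates.
#' @export
eval_schedule <- function(schedule, t) {
  t <- pmin(pmax(t, schedule$times[1]), schedule$times[length(schedule$times)])
  method <- if (schedule$interpolation == "linear") "linear" else "constant"
  out <- vapply(1:6, function(i) {
    col <- schedule$values[, i]
    if (all(col == 0)) return(rep(0, length(t)))
    stats::approx(schedule$times, col, xout = t, method = method,
                  rule = 2)$y
  }, numeric(length(t)))
  matrix(out, ncol = 6)
}

# flatten parameters into the layout expected by the compiled vector field
pack_parms <- function(params, fixed_w = FALSE) {
  curve_vec <- function(cv) c(cv$rb, cv$rm, cv$theta, cv$n)
  c(params$timescale, params$C_En, params$C_Nu,
    params$k1, params$k2, params$k3, params$k4,
    params$delta, params$b,
    unlist(lapply(params$regulation[REGULATION_PAIRS], curve_vec)),
    unlist(lapply(params$drugs, curve_vec)),
    as.numeric(fixed_w))
}

#' Simulate the model
#'
#' Integrates the 11-state system with an adaptive stiff-capable solver
#' (`deSolve::lsoda`). Returned states are clipped to the admissible box when
#' within integration tolerance of it; larger violations raise an error.
#'
#' @param params An [av_parameters()] object.
#' @param initial Initial state (length 11, see [av_state()]).
#' @param schedule A [control_schedule()] or `NULL` for no dosing.
#' @param times Output time grid (strictly increasing, minutes); the horizon
#'   must lie within the schedule domain.
#' @param fixed_w Optional length-6 vector: hold drug concentrations constant
#'   at these values (bypassing pharmacokinetics), as used for dose-response
#'   analysis.
#' @param rtol,atol Relative/absolute integration tolerances.
#' @return An `av_trajectory`: a data frame with columns `t`, `x1..x5`,
#'   `w1..w6` and attributes recording the parameters and schedule used.
#' @export
simulate_model <- function(params, initial, schedule = NULL, times,
                           fixed_w = NULL, rtol = 1e-8, atol = 1e-10) {
  validate_parameters(params)
  if (any(diff(times) <= 0)) stop("output grid must be strictly increasing")
  if (is.null(schedule)) schedule <- zero_schedule(max(times))
  if (max(times) > max(schedule$times) + 1e-9)
    stop("horizon extends beyond the schedule domain")
  y0 <- as.numeric(initial)
  if (length(y0) != 11L) stop("initial state must have 11 components")
  names(y0) <- STATE_NAMES
  if (!is.null(fixed_w)) y0[6:11] <- fixed_w
  forcings <- lapply(1:6, function(i)
    cbind(schedule$times, schedule$values[, i]))
  fcontrol <- list(method = if (schedule$interpolation == "linear")
    "linear" else "constant", rule = 2, f = 0)
  sol <- deSolve::lsoda(y0, times, func = "av_derivs",
                        parms = pack_parms(params, !is.null(fixed_w)),
                        dllname = "avctrl", initfunc = "av_initmod",
                        initforc = "av_initforc", forcings = forcings,
                        fcontrol = fcontrol, rtol = rtol, atol = atol)
  if (nrow(sol) < length(times))
    stop(sprintf("integration failed at t = %g min", sol[nrow(sol), 1]))
  out <- as.data.frame(sol)
  names(out) <- c("t", STATE_NAMES)
  # clip integrator ripple against the state box
  box_tol <- max(1e4 * atol, 1e-6)
  hi <- state_upper(params)
  for (j in seq_along(STATE_NAMES)) {
    v <- out[[j + 1]]
    if (any(v < -box_tol) || any(v > hi[j] + box_tol))
      stop("trajectory left the admissible state box: ", STATE_NAMES[j])
    out[[j + 1]] <- pmin(pmax(v, 0), hi[j])
  }
  structure(out, class = c("av_trajectory", "data.frame"),
            params = params, schedule = schedule)
}

#' Drug-free fixed point by root finding
#'
#' Newton iteration (with numerical fallback damping) on the drug-free
#' 5-state subsystem, used to obtain stationary initial conditions.
#'
#' @param params An [av_parameters()] object.
#' @param start Optional length-5 starting guess.
#' @return Length-11 state with zero drug concentrations.
#' @export
find_fixed_point <- function(params, start = NULL) {
  if (is.null(start)) start <- c(0.5, 0.5, 0.5, 0.5, av_ceiling(params) / 2)
  y <- c(start, rep(0, 6))
  for (it in 1:200) {
    X <- matrix(y, 11, 1)
    f <- vector_field_nodes(X, matrix(0, 6, 1), params)[1:5, 1]
    if (max(abs(f)) < 1e-12) break
    J <- vector_field_jacobian_nodes(X, matrix(0, 6, 1), params)$Jx[1:5, 1:5, 1]
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) stop("singular Jacobian in fixed-point search")
    lam <- 1
    repeat {
      y_new <- y
      y_new[1:5] <- pmin(pmax(y[1:5] + lam * step, 0),
                         c(rep(1, 4), av_ceiling(params)))
      Xn <- matrix(y_new, 11, 1)
      fn <- vector_field_nodes(Xn, matrix(0, 6, 1), params)[1:5, 1]
      if (sum(fn^2) < sum(f^2) || lam < 1e-6) break
      lam <- lam / 2
    }
    y <- y_new
  }
  names(y) <- STATE_NAMES
  y
}

#' Export a trajectory to CSV
#' @param trajectory An `av_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE)
  invisible(path)
}
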