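#' Solve a minimum-fuel therapy design problem
#'
#' Transcribes the problem on an LGL grid (see [transcribe()]) and solves the
#' resulting nonlinear program with the package's augmented-Lagrangian
#' backend: projected Gauss-Newton inner minimizations (dense defect
#' Jacobian, direct Cholesky solves, Levenberg-Marquardt damping) inside a
#' classical multiplier/penalty outer loop on the defect equalities. The
#' deliverable staircase schedule is extracted so exact pharmacokinetic
#' integration reproduces the optimal concentration profile, aligned and
#' polished against the true integrator, and validated by independent
#' re-integration ([validate_solution()]); the solver retries nearby grid
#' orders and stiffer initial penalties when validation fails.
#'
#' The initial guess is a constant maintenance dose (bisected on the
#' simulated window-average AV count) simulated forward; optional seeded
#' multi-start perturbs that guess.
#'
#' @param spec An [ocp_spec()].
#' @param N Collocation order (default 48).
#' @param u_max Injection-rate cap passed to [transcribe()].
#' @param band_margin Band tightening passed to [transcribe()].
#' @param entry_lead Minutes before `t0` from which the band is enforced in
#'   the transcription and polish (entry safeguard; validation still uses
#'   `[t0, tf]`).
#' @param feas_tol Scaled defect infeasibility target.
#' @param opt_tol Inner projected-gradient tolerance (passed to L-BFGS-B as
#'   `factr`-independent `pgtol`).
#' @param max_outer Maximum outer multiplier updates.
#' @param inner_maxit L-BFGS-B iteration cap per inner solve.
#' @param mu0,mu_growth Initial penalty weight and growth factor.
#' @param n_starts Number of multi-start attempts (first uses the unperturbed
#'   guess).
#' @param seed Seed for multi-start perturbations (recorded in the solution).
#' @param validation_tol Band-violation threshold (AV units) below which a
#'   converged NLP is reported as `"solved"`.
#' @param verbose Print outer-iteration progress.
#' @return An `ocp_solution`: list with `status` (`"solved"`; `"feasible"`
#'   when the validated schedule meets all constraints but the NLP stopped
#'   short of its convergence tolerances; `"converged_infeasible"`;
#'   `"max_iterations"`; `"infeasible"`), node matrices `X` (states) and
#'   `U` (controls), the interpolated `schedule` and `trajectory`, objective
#'   `J`, `dosage` record, `feasibility` report, defect residual norm,
#'   multiplier estimates, iteration counts and the transcription used.
#' @export
solve_ocp <- function(spec, N = 48, u_max = 10, band_margin = 0.25,
                      entry_lead = 0,
                      feas_tol = 1e-5, opt_tol = 1e-6, max_outer = 30,
                      inner_maxit = 200, mu0 = 1e4, mu_growth = 5,
                      n_starts = 1, seed = 1L, validation_tol = 0.05,
                      verbose = FALSE) {
  stopifnot(inherits(spec, "ocp_spec"))
  if (spec$target >= av_ceiling(spec$params))
    return(structure(list(status = "infeasible",
                          reason = "target at or above the AV-count ceiling"),
                     class = "ocp_solution"))
  attempt <- function(N_try, mu0_try) {
    nlp <- transcribe(spec, N_try, u_max = u_max, band_margin = band_margin,
                      entry_lead = entry_lead)
    grid <- nlp$grid
    m <- nlp$m
    # initial guess: a constant maintenance dose (found by bisection on the
    # simulated window-average AV count) simulated forward, so the guess
    # starts near dynamic feasibility with the band approximately met
    guess <- maintenance_guess(spec, u_max)
    tr0 <- simulate_model(spec$params, spec$initial, guess$schedule,
                          times = sort(unique(c(0, grid$times))))
    X0 <- as.matrix(tr0[match(round(grid$times, 9), round(tr0$t, 9)), -1])
    U0 <- matrix(0, m, 6)
    U0[, spec$therapy] <- rep(guess$u[spec$therapy], each = m)
    z0_base <- pmin(pmax(nlp$pack(X0, U0), nlp$lower), nlp$upper)

    best <- NULL
    for (s in seq_len(n_starts)) {
      z0 <- z0_base
      if (s > 1) {
        pert <- stats::rnorm(nlp$n_var, sd = 0.05)
        z0 <- pmin(pmax(z0_base + pert, nlp$lower), nlp$upper)
      }
      res <- auglag_box(z0, nlp, feas_tol = feas_tol, opt_tol = opt_tol,
                        max_outer = max_outer, inner_maxit = inner_maxit,
                        mu0 = mu0_try, mu_growth = mu_growth,
                        verbose = verbose)
      if (is.null(best) ||
          (res$converged && !best$converged) ||
          (res$converged == best$converged && res$J < best$J))
        best <- res
    }

    sol <- nlp$unpack(best$z)
    sched <- pk_consistent_schedule(sol$X, sol$U, spec, grid, u_max)
    report <- validate_solution(spec, sched)
    # The collocation solution is optimal for the discretized dynamics, but
    # its re-integrated trajectory can miss the band: the descent to the
    # target traverses a dynamically unstable stretch of the kinase
    # network, so representation error surfaces mostly as a late band
    # entry. Alternate (i) advancing the schedule by the measured entry
    # delay with (ii) Gauss-Newton polish of the staircase rates against
    # the true integrator until the validated violation is in tolerance.
    if (best$cnorm < 1e-3) {
      for (round in 1:3) {
        if (report$band_violation <= 0.5 * validation_tol) break
        delay <- entry_delay(spec, report$trajectory, band_margin)
        if (is.finite(delay) && delay > 0.1 && delay < 30) {
          shifted <- shift_schedule(sched, delay)
          rep_s <- validate_solution(spec, shifted)
          if (rep_s$band_violation < report$band_violation) {
            sched <- shifted
            report <- rep_s
          }
        }
        polished <- polish_schedule(spec, sched, u_max,
                                    band_margin = band_margin,
                                    verbose = verbose)
        rep2 <- validate_solution(spec, polished)
        if (rep2$band_violation < report$band_violation) {
          sched <- polished
          report <- rep2
        } else if (!(is.finite(delay) && delay > 0.1)) break
      }
    }
    list(nlp = nlp, grid = grid, best = best, sol = sol, sched = sched,
         report = report)
  }

  # retry over nearby grid orders and stiffer initial penalties when
  # validation fails: the minimum-fuel solutions are non-smooth and
  # individual configurations can settle on poorly re-integrating or
  # control-collapsed local optima
  set.seed(as.integer(seed))
  feasible <- function(cand)
    cand$report$band_violation <= validation_tol &&
      max(cand$report$cap_violation) <= validation_tol
  configs <- list(c(N, mu0), c(N, 10 * mu0), c(N + 6, mu0),
                  c(max(24, N - 6), 10 * mu0))
  chosen <- NULL
  for (cfg in configs) {
    cand <- attempt(cfg[1], cfg[2])
    better <- if (is.null(chosen)) TRUE
      else if (feasible(cand) != feasible(chosen)) feasible(cand)
      else if (feasible(cand)) {
        J_c <- schedule_objective(cand$sched, spec$therapy, spec$tf)
        J_b <- schedule_objective(chosen$sched, spec$therapy, spec$tf)
        (cand$best$converged && !chosen$best$converged) ||
          (cand$best$converged == chosen$best$converged && J_c < J_b)
      } else cand$report$band_violation < chosen$report$band_violation
    if (better) chosen <- cand
    if (feasible(chosen) && chosen$best$converged) break
  }
  nlp <- chosen$nlp; grid <- chosen$grid; best <- chosen$best
  sol <- chosen$sol; sched <- chosen$sched; report <- chosen$report
  J <- schedule_objective(sched, spec$therapy, spec$tf)
  dosage <- cumulative_dosage(sched, spec$therapy,
                              seq(0, spec$tf, length.out = 961))
  validated <- report$band_violation <= validation_tol &&
    max(report$cap_violation) <= validation_tol
  status <- if (validated && best$converged) {
    "solved"
  } else if (validated) {
    "feasible"
  } else if (best$converged) "converged_infeasible" else "max_iterations"
  structure(list(status = status, spec = spec, grid = grid,
                 X = sol$X, U = sol$U, schedule = sched,
                 trajectory = report$trajectory, J = J,
                 quadrature_J = J, dosage = dosage, feasibility = report,
                 defect_norm = best$cnorm, multipliers = best$lambda,
                 outer_iterations = best$outer, inner_evals = best$evals,
                 nlp = nlp, seed = seed, u_max = u_max),
            class = "ocp_solution")
}

#' @export
print.ocp_solution <- function(x, ...) {
  if (identical(x$status, "infeasible")) {
    cat("<ocp_solution infeasible: ", x$reason, ">\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf(paste0("<ocp_solution %s J=%.4f band=%.3g defects=%.2e ",
                     "outer=%d>\n"),
              x$status, x$J, x$feasibility$band_violation, x$defect_norm,
              x$outer_iterations))
  invisible(x)
}

# Extract the deliverable schedule from the collocation solution as a
# staircase: one constant injection rate per node interval (the natural form
# for near-impulsive minimum-fuel solutions). Sampling the node controls
# directly would leave a spectral-vs-piecewise representation mismatch;
# because the pharmacokinetics are linear (T w' = u - delta w), the interval
# rates are instead chosen so that exact integration reproduces the NLP's
# optimal concentration profile w at every node:
#   w[k+1] = w[k] E + u_k (1 - E) / (d T),   E = exp(-d h),  d = delta / T,
# solved per interval and clamped to [0, u_max].
pk_consistent_schedule <- function(X, U, spec, grid, u_max, refine = 4L) {
  params <- spec$params
  # refined staircase grid: the collocation w-polynomial is matched on
  # sub-intervals so the intra-interval concentration mismatch (which the
  # steep dose sensitivity amplifies) stays second order in the sub-step
  tt <- grid$times
  tfine <- sort(unique(as.numeric(vapply(seq_len(length(tt) - 1), function(k)
    seq(tt[k], tt[k + 1], length.out = refine + 1L)[-(refine + 1L)],
    numeric(refine)))))
  tfine <- c(tfine, tt[length(tt)])
  mf <- length(tfine)
  out <- matrix(0, mf, 6)
  for (i in spec$therapy) {
    d <- params$delta[i] / params$timescale
    w <- pmax(interpolate_nodes(grid, X[, 5 + i], tfine), 0)
    h <- diff(tfine)
    E <- exp(-d * h)
    u <- numeric(mf - 1)
    w_real <- w[1]
    for (k in seq_len(mf - 1)) {
      u[k] <- min(max((w[k + 1] - w_real * E[k]) * d * params$timescale /
                        (1 - E[k]), 0), u_max)
      w_real <- w_real * E[k] + u[k] * (1 - E[k]) / (d * params$timescale)
    }
    out[, i] <- c(u, 0)
  }
  control_schedule(tfine, out, interpolation = "constant")
}

# advance a staircase schedule in time by `delay` minutes (rates are read
# at the shifted midpoints; the horizon end is padded with zero input)
shift_schedule <- function(schedule, delay) {
  tt <- schedule$times
  mids <- (tt[-length(tt)] + tt[-1]) / 2
  vals <- rbind(eval_schedule(schedule, pmin(mids + delay, max(tt))), 0)
  tail_off <- mids + delay > max(tt)
  vals[c(tail_off, FALSE), ] <- 0
  control_schedule(tt, vals, interpolation = "constant")
}

# First time after t0 at which the re-integrated AV count has settled
# inside the (slightly tightened) band, minus t0: the schedule advance that
# would align the band entry. Inf when the trajectory never settles.
entry_delay <- function(spec, trajectory, band_margin) {
  t <- trajectory$t
  inside <- abs(trajectory$x5 - spec$target) <=
    (spec$epsilon - 0.5 * band_margin)
  ok <- which(inside & t >= spec$t0 - 30)
  if (!length(ok)) return(Inf)
  max(0, t[ok[1]] - spec$t0)
}

# Single-shooting polish of a staircase schedule against the adaptive
# integrator used for validation: damped Gauss-Newton (finite-difference
# Jacobian, Broyden-refreshed) on softplus-smoothed hinge residuals of the
# band constraint over [t0, tf], a mild pull toward the band center, and
# concentration-cap overshoots; interval rates clamped to [0, u_max].
polish_schedule <- function(spec, schedule, u_max, band_margin = 0.1,
                            max_iter = 25, n_check = 241,
                            verbose = FALSE) {
  times <- schedule$times
  m <- length(times)
  therapy <- spec$therapy
  k <- length(therapy)
  v0 <- as.numeric(schedule$values[seq_len(m - 1), therapy])
  lo_b <- spec$target - (spec$epsilon - 0.5 * band_margin)
  hi_b <- spec$target + (spec$epsilon - 0.5 * band_margin)
  tq <- sort(unique(c(seq(0, spec$tf, length.out = n_check), spec$t0)))
  in_win <- tq >= spec$t0 - 1e-9
  w_cap <- spec$w_max[therapy] * (1 - 1e-3)
  smooth <- 0.03
  softplus <- function(x)
    ifelse(x > 30 * smooth, x, smooth * log1p(exp(pmin(x / smooth, 30))))
  make_sched <- function(v) {
    vals <- matrix(0, m, 6)
    vals[seq_len(m - 1), therapy] <- pmin(pmax(matrix(v, ncol = k), 0),
                                          u_max)
    control_schedule(times, vals, interpolation = "constant")
  }
  sim <- function(v, rtol = 1e-8, atol = 1e-10)
    simulate_model(spec$params, spec$initial, make_sched(v), tq,
                   rtol = rtol, atol = atol)
  resid <- function(v) {
    tr <- sim(v)
    x5 <- tr$x5[in_win]
    r_band <- softplus(x5 - hi_b) - softplus(lo_b - x5)
    # mild pull toward the band center regularizes the weakly damped
    # ringing modes that pure violation residuals cannot see
    r_track <- 0.15 * (x5 - spec$target) / max(1, spec$epsilon)
    r_cap <- as.numeric(vapply(seq_len(k), function(j)
      pmax(tr[[paste0("w", therapy[j])]] - w_cap[j], 0),
      numeric(length(tq))))
    c(r_band, r_track, r_cap)
  }
  true_violation <- function(v) {
    x5 <- sim(v)$x5[in_win]
    max(0, x5 - (spec$target + spec$epsilon),
        (spec$target - spec$epsilon) - x5)
  }
  fd_jacobian <- function(v, r0) {
    Jm <- matrix(0, length(r0), length(v))
    for (j in seq_along(v)) {
      h <- 1e-3 * (abs(v[j]) + 0.01)
      vp <- v; vp[j] <- vp[j] + h
      Jm[, j] <- (resid(vp) - r0) / h
    }
    Jm
  }
  v <- pmin(pmax(v0, 0), u_max)
  r <- resid(v)
  best_v <- v; best_norm <- true_violation(v)
  Jm <- NULL
  since_fd <- Inf
  rho <- 1e-3
  for (it in seq_len(max_iter)) {
    tv <- true_violation(v)
    if (tv < best_norm) { best_v <- v; best_norm <- tv }
    if (tv < min(0.5 * band_margin, 0.04)) break
    fresh <- FALSE
    if (is.null(Jm) || since_fd >= 4) {
      Jm <- fd_jacobian(v, r)
      since_fd <- 0L
      fresh <- TRUE
    }
    G <- crossprod(Jm)
    gscale <- max(1e-8, max(abs(diag(G))))
    improved <- FALSE
    for (tries in 1:6) {
      H <- G + diag(rho * gscale, length(v))
      step <- tryCatch(-solve(H, drop(crossprod(Jm, r))),
                       error = function(e) NULL)
      if (is.null(step)) { rho <- rho * 10; next }
      v_new <- pmin(pmax(v + step, 0), u_max)
      r_new <- resid(v_new)
      if (sum(r_new^2) < sum(r^2)) {
        dv <- v_new - v
        if (sum(dv^2) > 0)   # Broyden rank-1 refresh between FD rebuilds
          Jm <- Jm + ((r_new - r - Jm %*% dv) %*% t(dv)) / sum(dv^2)
        v <- v_new; r <- r_new
        rho <- max(rho / 3, 1e-6)
        improved <- TRUE
        break
      }
      rho <- rho * 10
    }
    since_fd <- since_fd + 1L
    if (verbose)
      message(sprintf("  polish %2d: residual %.4f violation %.4f", it,
                      max(abs(r)), true_violation(v)))
    if (!improved && fresh) break
    if (!improved) Jm <- NULL
  }
  tvf <- true_violation(v)
  if (tvf < best_norm) { best_v <- v; best_norm <- tvf }
  make_sched(best_v)
}


# Constant-dose warm start: bisect a common dose scale s (w_i = s * theta_i
# for therapy drugs, injected at the replacement rate u_i = delta_i * w_i)
# until the simulated end-point AV count brackets the target.
maintenance_guess <- function(spec, u_max) {
  params <- spec$params
  therapy <- spec$therapy
  theta <- vapply(params$drugs, function(cv) cv$theta, numeric(1))
  s_hi <- min(0.9 * spec$w_max[therapy] / theta[therapy],
              0.9 * u_max / (params$delta[therapy] * theta[therapy]))
  x5_end <- function(s) {
    u <- rep(0, 6)
    u[therapy] <- params$delta[therapy] * s * theta[therapy]
    sched <- control_schedule(c(0, spec$tf), rbind(u, u))
    tr <- simulate_model(params, spec$initial, sched,
                         times = seq(0, spec$tf, length.out = 241),
                         rtol = 1e-6, atol = 1e-8)
    mean(tr$x5[tr$t >= spec$t0])
  }
  base <- x5_end(1e-6)
  full <- x5_end(s_hi)
  want_down <- spec$target < base
  lo <- 1e-6; hi <- s_hi
  # monotone bracketing; if even the strongest dose misses the target the
  # strongest available dose is used and the NLP does the rest
  if ((want_down && full < spec$target) || (!want_down && full > spec$target)) {
    for (it in 1:30) {
      mid <- sqrt(lo * hi)
      v <- x5_end(mid)
      if ((v > spec$target) == want_down) lo <- mid else hi <- mid
      if (hi / lo < 1.01) break
    }
    s <- sqrt(lo * hi)
  } else {
    s <- s_hi
  }
  u <- rep(0, 6)
  u[therapy] <- params$delta[therapy] * s * theta[therapy]
  list(u = u, s = s,
       schedule = control_schedule(c(0, spec$tf), rbind(u, u)))
}

# Augmented-Lagrangian loop for a transcribed NLP:
# minimize f(z) s.t. c(z) = 0, lower <= z <= upper.
# Inner subproblems are solved by projected Gauss-Newton: the penalty
# Hessian mu * A'A (A the dense defect Jacobian) is factorized directly on
# the inactive variables, which copes with the severe conditioning of
# spectral differentiation that defeats limited-memory quasi-Newton updates.
auglag_box <- function(z0, nlp, feas_tol, opt_tol, max_outer, inner_maxit,
                       mu0, mu_growth, verbose = FALSE) {
  lambda <- numeric(nlp$n_con)
  mu <- mu0
  z <- z0
  cnorm_prev <- Inf
  evals <- 0L
  converged <- FALSE
  eta <- 1e-2
  for (outer in seq_len(max_outer)) {
    inner <- gauss_newton_inner(z, nlp, lambda, mu, inner_maxit, opt_tol)
    z <- inner$z
    evals <- evals + inner$iters
    cc <- nlp$constraints(z)
    cnorm <- max(abs(cc))
    if (verbose)
      message(sprintf("  outer %2d: J=%.5f |c|=%.3e mu=%.1e inner=%d",
                      outer, nlp$objective(z), cnorm, mu, inner$iters))
    if (cnorm < feas_tol) {
      lambda <- lambda + mu * cc
      converged <- TRUE
      break
    }
    # multiplier update only on sufficient feasibility progress, else
    # sharpen the penalty (classical augmented-Lagrangian safeguard)
    if (cnorm <= max(eta, feas_tol)) {
      lambda <- lambda + mu * cc
      eta <- eta * 0.2
    } else {
      mu <- mu * mu_growth
    }
    # stop once the penalty escalation has stopped buying feasibility
    if (cnorm > 0.9 * cnorm_prev && mu > 1e12) break
    cnorm_prev <- min(cnorm_prev, cnorm)
  }
  list(z = z, lambda = lambda, cnorm = max(abs(nlp$constraints(z))),
       J = nlp$objective(z), outer = outer, evals = as.integer(evals),
       converged = converged)
}

# Projected Gauss-Newton minimization of the augmented Lagrangian
# phi(z) = J(z) + lambda'c(z) + mu/2 |c(z)|^2 over the bound box.
gauss_newton_inner <- function(z, nlp, lambda, mu, maxit, opt_tol) {
  lower <- nlp$lower; upper <- nlp$upper
  phi <- function(zz) {
    cc <- nlp$constraints(zz)
    nlp$objective(zz) + sum(lambda * cc) + mu / 2 * sum(cc^2)
  }
  f <- phi(z)
  kkt <- Inf
  rho <- 1e-3 * mu     # Levenberg-Marquardt proximal damping
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    cc <- nlp$constraints(z)
    A <- nlp$constraint_jacobian(z)
    g <- nlp$gradient(z) + drop(crossprod(A, lambda + mu * cc))
    # projected-gradient KKT measure
    pg <- g
    pg[z <= lower + 1e-12 & g > 0] <- 0
    pg[z >= upper - 1e-12 & g < 0] <- 0
    kkt <- max(abs(pg))
    if (kkt <= max(opt_tol, 1e-9 * mu)) break
    # epsilon-active bounds stay fixed for this step
    act <- (z <= lower + 1e-9 & g > 0) | (z >= upper - 1e-9 & g < 0) |
      (upper - lower < 1e-12)
    free <- which(!act)
    if (!length(free)) break
    Af <- A[, free, drop = FALSE]
    H <- mu * crossprod(Af)
    accepted <- FALSE
    for (tries in 1:10) {
      ch <- tryCatch(chol(H + diag(rho, nrow(H))), error = function(e) NULL)
      if (is.null(ch)) { rho <- rho * 10; next }
      step <- -backsolve(ch, forwardsolve(t(ch), g[free]))
      z_new <- z
      z_new[free] <- z[free] + step
      z_new <- pmin(pmax(z_new, lower), upper)
      f_new <- phi(z_new)
      if (is.finite(f_new) && f_new < f - 1e-12 * abs(f)) {
        z <- z_new; f <- f_new
        rho <- max(rho / 3, 1e-8 * mu)
        accepted <- TRUE
        break
      }
      rho <- rho * 10
    }
    if (!accepted) break
  }
  list(z = z, iters = it, kkt = kkt)
}

#' First-order optimality diagnostics for a solved schedule
#'
#' Recovers costate estimates from the defect-constraint multipliers through
#' the quadrature weights (the costate at node k for state s is
#' `-nu[k, s] / wq[k]`, with `nu` the unscaled defect multiplier), evaluates
#' each therapy drug's switching function (the coefficient of its injection
#' rate in the Hamiltonian, `1 + costate_w_i / T`), and reports the
#' complementarity residual `max_k u_i[k] * max(0, sigma_i[k])`: for a
#' minimum-fuel solution, drug is injected only where its switching function
#' is non-positive.
#'
#' @param solution A solved `ocp_solution` (status `"solved"`).
#' @return An `optimality_diagnostics` list: `costates` (node matrix),
#'   `switching` (nodes x therapy), `complementarity_residual`.
#' @export
check_necessary_conditions <- function(solution) {
  stopifnot(inherits(solution, "ocp_solution"))
  if (!identical(solution$status, "solved"))
    stop("diagnostics require a solution with status 'solved'")
  if (is.null(solution$multipliers)) stop("multipliers unavailable")
  nlp <- solution$nlp
  grid <- solution$grid
  m <- nlp$m
  # unscale: lagrangian term sum(lambda_scaled * c_scaled) =
  #          sum(nu * c_unscaled) with nu = lambda_scaled / defect_scale
  nu <- sweep(matrix(solution$multipliers, m, 11), 2, nlp$defect_scale, "/")
  # objective carries a factor beta * wq per node; normalize multipliers to
  # the running-cost scale before reading off costates
  costates <- -nu / (grid$half_span * grid$weights)
  Tsc <- solution$spec$params$timescale
  therapy <- solution$spec$therapy
  switching <- matrix(0, m, length(therapy))
  for (j in seq_along(therapy)) {
    switching[, j] <- 1 + costates[, 5 + therapy[j]] / Tsc
  }
  u_act <- solution$U[, therapy, drop = FALSE]
  comp <- max(0, u_act * pmax(switching, 0))
  structure(list(costates = costates, switching = switching,
                 therapy = therapy,
                 complementarity_residual = max(comp)),
            class = "optimality_diagnostics")
}

#' Minimal horizon fraction holding a given share of the total dosage
#'
#' Sorts the sampled total injection rate in decreasing order and reports
#' the smallest fraction of the horizon whose (highest-rate) time points
#' deliver at least `share` of the total dosage. Impulsive, staircase-like
#' schedules concentrate dosage in short bursts and score low; constant
#' infusion scores `share` itself.
#'
#' @param schedule A [control_schedule()].
#' @param therapy Drug indices to include.
#' @param tf Horizon end.
#' @param share Dosage share to cover (default 0.8).
#' @param n_grid Sampling resolution.
#' @return A fraction in `[0, 1]` (NA for an all-zero schedule).
#' @export
dosage_time_fraction <- function(schedule, therapy, tf, share = 0.8,
                                 n_grid = 4801) {
  therapy <- check_therapy(therapy)
  tq <- seq(0, tf, length.out = n_grid)
  u <- rowSums(eval_schedule(schedule, tq)[, therapy, drop = FALSE])
  total <- sum(u)
  if (total <= 0) return(NA_real_)
  u_sorted <- sort(u, decreasing = TRUE)
  n_needed <- which(cumsum(u_sorted) >= share * total)[1]
  n_needed / n_grid
}

#' Detect injection pulses and summarize staircase structure
#'
#' Finds the time intervals where a schedule's total injection rate exceeds
#' `threshold_frac` of its peak and reports the fraction of the horizon they
#' cover and the fraction of the total dosage delivered inside them. Optimal
#' minimum-fuel schedules concentrate dosage in short pulses, producing
#' staircase-shaped cumulative dosage curves.
#'
#' @param schedule A [control_schedule()].
#' @param therapy Drug indices to include.
#' @param tf Horizon end.
#' @param threshold_frac Pulse detection threshold, relative to the peak rate.
#' @param n_grid Sampling resolution.
#' @return List with `pulse_fraction` (share of `[0, tf]` covered by
#'   pulses), `dosage_fraction` (share of total dosage inside pulses),
#'   `first_dose_time` (first time the rate exceeds the threshold), and the
#'   pulse `intervals`.
#' @export
pulse_summary <- function(schedule, therapy, tf, threshold_frac = 0.05,
                          n_grid = 4801) {
  therapy <- check_therapy(therapy)
  tq <- seq(0, tf, length.out = n_grid)
  u <- rowSums(eval_schedule(schedule, tq)[, therapy, drop = FALSE])
  peak <- max(u)
  if (peak <= 0)
    return(list(pulse_fraction = 0, dosage_fraction = NA_real_,
                first_dose_time = NA_real_, intervals = NULL))
  on <- u > threshold_frac * peak
  dt <- tq[2] - tq[1]
  total <- sum(u) * dt
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  iv <- cbind(tq[starts[runs$values]], tq[ends[runs$values]])
  list(pulse_fraction = sum(on) / length(on),
       dosage_fraction = sum(u[on]) * dt / total,
       first_dose_time = tq[which(on)[1]],
       intervals = iv)
}
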