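#' Transcribe an optimal-control problem to a nonlinear program
#'
#' Legendre-Gauss-Lobatto pseudo-spectral transcription. The full horizon
#' `[0, tf]` is discretized on one LGL grid; decision variables are the 11
#' states and the therapy's controls at every node. The dynamics become
#' defect equalities
#' `sum_i D[k, i] X[i, s] - (tf - 0)/2 * f_s(X[k], u[k]) = 0`
#' at every node `k` and state `s`; the running cost becomes the LGL
#' quadrature `(tf - 0)/2 * sum_k wq[k] * sum_j u[j, k]`.
#'
#' Every inequality of the problem maps to a simple bound on a decision
#' variable: kinase fractions in `[0, 1]`, the AV count in `[0, k3/k4]`
#' tightened to the target band (shrunk by `band_margin`, a discretization
#' safety margin for the continuous-time constraint) at nodes whose mapped
#' time reaches `t0`, drug concentrations in `[0, w_max]` (pinned to 0 for
#' unavailable drugs), controls in `[0, u_max]`, and the initial state pinned
#' to its prescribed value.
#'
#' Defects are scaled per state by `(tf/2) * state_scale` and variables by
#' their natural magnitudes, so residuals are relative rates of order one.
#'
#' @param spec An [ocp_spec()].
#' @param grid A [lgl_grid()] on `[0, tf]`; a bare integer is accepted and
#'   expanded to `lgl_grid(N, 0, spec$tf)`.
#' @param u_max Upper bound on each injection rate (concentration units per
#'   minute); finite to keep the minimum-fuel NLP bounded while preserving
#'   near-impulsive pulses.
#' @param band_margin Amount by which the band half-width is shrunk at the
#'   collocation nodes (AV units).
#' @param entry_lead Minutes before `t0` from which the band is already
#'   enforced (guards the band entry against discretization error; the
#'   validated constraint remains the window `[t0, tf]`).
#' @return A `transcribed_nlp`: list with the variable layout, scaled bounds
#'   `lower`/`upper`, functions `objective(z)`, `gradient(z)`,
#'   `constraints(z)` (scaled defect vector) and `constraint_jac_t(z, v)`
#'   (transposed-Jacobian product), plus helpers `unpack(z)` and `pack(X, U)`.
#' @export
transcribe <- function(spec, grid, u_max = 10, band_margin = 0.05,
                       entry_lead = 0) {
  stopifnot(inherits(spec, "ocp_spec"))
  if (is.numeric(grid) && length(grid) == 1L)
    grid <- lgl_grid(grid, 0, spec$tf)
  stopifnot(inherits(grid, "collocation_grid"))
  if (abs(grid$t0) > 1e-12 || abs(grid$tf - spec$tf) > 1e-9)
    stop("grid must span [0, tf]")
  params <- spec$params
  therapy <- spec$therapy
  m <- grid$N + 1
  k <- length(therapy)
  in_band <- grid$times >= spec$t0 - entry_lead - 1e-9
  if (!any(in_band))
    stop("grid too coarse: no collocation node at or beyond t0")
  ceil <- av_ceiling(params)
  beta <- grid$half_span

  # state bounds per node (m x 11)
  lower_X <- matrix(0, m, 11)
  upper_X <- matrix(rep(c(rep(1, 4), ceil, spec$w_max), each = m), m, 11)
  upper_X[, 5 + setdiff(1:6, therapy)] <- 0
  eps_nlp <- spec$epsilon - band_margin
  if (eps_nlp <= 0) stop("'band_margin' must be smaller than epsilon")
  down <- spec$target <= spec$initial[5]
  if (!spec$one_sided || down)
    upper_X[in_band, 5] <- spec$target + eps_nlp
  if (!spec$one_sided || !down)
    lower_X[in_band, 5] <- spec$target - eps_nlp
  lower_X[1, ] <- upper_X[1, ] <- spec$initial   # pinned initial state

  state_scale <- c(rep(1, 4), ceil,
                   pmax(1, ifelse(is.finite(spec$w_max), spec$w_max, 1)))
  var_scale <- c(rep(state_scale, each = m), rep(u_max, m * k))
  defect_scale <- beta * state_scale

  nX <- m * 11
  nz <- nX + m * k
  wq <- grid$weights

  unpack <- function(z) {
    z <- z * var_scale
    X <- matrix(z[seq_len(nX)], m, 11)
    U6 <- matrix(0, m, 6)
    if (k > 0) U6[, therapy] <- matrix(z[nX + seq_len(m * k)], m, k)
    list(X = X, U = U6)
  }
  pack <- function(X, U6) {
    c(as.numeric(X), as.numeric(U6[, therapy, drop = FALSE])) / var_scale
  }

  grad_J <- numeric(nz)
  if (k > 0) grad_J[nX + seq_len(m * k)] <- rep(beta * wq, k) *
    var_scale[nX + seq_len(m * k)]

  objective <- function(z) {
    if (k == 0) return(0)
    u <- matrix(z[nX + seq_len(m * k)] * var_scale[nX + seq_len(m * k)], m, k)
    beta * sum(wq * rowSums(u))
  }
  gradient <- function(z) grad_J

  constraints <- function(z) {
    s <- unpack(z)
    f <- t(vector_field_nodes(t(s$X), t(s$U), params))    # m x 11
    defects <- grid$D %*% s$X - beta * f
    as.numeric(sweep(defects, 2, defect_scale, "/"))
  }

  # t(J_c) %*% v for a defect-multiplier vector v (length m * 11)
  constraint_jac_t <- function(z, v) {
    s <- unpack(z)
    V <- sweep(matrix(v, m, 11), 2, defect_scale, "/")
    jac <- vector_field_jacobian_nodes(t(s$X), t(s$U), params)
    gX <- crossprod(grid$D, V)                   # D^T V part
    for (kk in seq_len(m)) {
      gX[kk, ] <- gX[kk, ] - beta * as.numeric(V[kk, ] %*% jac$Jx[, , kk])
    }
    gU <- matrix(0, m, 6)
    for (kk in seq_len(m)) {
      gU[kk, ] <- -beta * as.numeric(V[kk, ] %*% jac$Ju[, , kk])
    }
    c(as.numeric(gX), as.numeric(gU[, therapy, drop = FALSE])) * var_scale
  }

  # dense constraint Jacobian d c_scaled / d z_scaled (n_con x n_var)
  constraint_jacobian <- function(z) {
    s <- unpack(z)
    jac <- vector_field_jacobian_nodes(t(s$X), t(s$U), params)
    A <- matrix(0, m * 11, nz)
    for (ss in 1:11) {
      rows <- (ss - 1) * m + seq_len(m)
      A[rows, (ss - 1) * m + seq_len(m)] <- grid$D
      for (sp in 1:11) {
        cols <- (sp - 1) * m + seq_len(m)
        dd <- -beta * jac$Jx[ss, sp, ]
        if (any(dd != 0))
          A[cbind(rows, cols)] <- A[cbind(rows, cols)] + dd
      }
      for (j in seq_len(k)) {
        cols <- nX + (j - 1) * m + seq_len(m)
        dd <- -beta * jac$Ju[ss, therapy[j], ]
        if (any(dd != 0)) A[cbind(rows, cols)] <- dd
      }
      A[rows, ] <- A[rows, ] / defect_scale[ss]
    }
    sweep(A, 2, var_scale, "*")
  }

  structure(list(
    spec = spec, grid = grid, therapy = therapy, m = m, k = k,
    n_var = nz, n_con = m * 11,
    u_max = u_max, band_margin = band_margin,
    var_scale = var_scale, defect_scale = defect_scale,
    lower = pack(lower_X, {
      L <- matrix(0, m, 6); L
    }),
    upper = pack(upper_X, {
      U <- matrix(0, m, 6); U[, therapy] <- u_max; U
    }),
    objective = objective, gradient = gradient,
    constraints = constraints, constraint_jac_t = constraint_jac_t,
    constraint_jacobian = constraint_jacobian,
    unpack = unpack, pack = pack),
    class = "transcribed_nlp")
}

#' @export
print.transcribed_nlp <- function(x, ...) {
  cat(sprintf("<transcribed_nlp N=%d, %d variables, %d defect constraints>\n",
              x$grid$N, x$n_var, x$n_con))
  invisible(x)
}
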